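test_that("MediaPipe CSV reads preserve frame order and all 33 landmarks", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mediapipe_fixture(f, frames = 1)
  seq1 <- read_mediapipe(f)
  expect_s3_class(seq1, "pose_sequence")
  expect_equal(dim(seq1$coords), c(1, 33, 3))
  expect_identical(seq1$dialect, "mediapipe33")

  write_mediapipe_fixture(f, frames = 10)
  seq10 <- read_mediapipe(f)
  expect_equal(dim(seq10$coords)[1], 10)
  expect_identical(seq10$frames, 0:9)
})

test_that("MediaPipe JSON-lines round gives the same coordinates as CSV", {
  fc <- withr::local_tempfile(fileext = ".csv")
  write_mediapipe_fixture(fc, frames = 3)
  from_csv <- read_mediapipe(fc)

  fj <- withr::local_tempfile(fileext = ".jsonl")
  lines <- vapply(1:3, function(t) {
    lm <- lapply(1:33, function(j) {
      as.list(setNames(c(from_csv$coords[t, j, ], 1),
                       c("x", "y", "z", "visibility")))
    })
    jsonlite::toJSON(list(frame = t - 1L, landmarks = lm),
                     auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, fj)
  from_json <- read_mediapipe(fj)
  expect_equal(from_json$coords, from_csv$coords)
})

test_that("a frame missing a landmark is a parse error naming the frame", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mediapipe_fixture(f, frames = 3, drop_landmark = 27)
  expect_error(read_mediapipe(f), "frame 1.*27")
  writeLines("frame,landmark,x,y,z", f)
  expect_error(read_mediapipe(f), "empty")
})

test_that("COCO-18 reader stores confidence as visibility, has no z", {
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_fixture(f)
  seq <- read_coco18(f)
  expect_equal(dim(seq$coords), c(3, 18, 2))
  expect_identical(seq$dialect, "coco18")
  expect_equal(unique(as.vector(seq$visibility)), 0.9)
})

test_that("COCO-18 reader drops empty frames and rejects multi-person frames", {
  f <- withr::local_tempfile(fileext = ".json")
  write_coco_fixture(f, n_people = c(1, 0, 1))
  expect_warning(seq <- read_coco18(f), "no person")
  expect_equal(dim(seq$coords)[1], 2)
  expect_identical(seq$frames, c(0L, 2L))

  write_coco_fixture(f, n_people = c(1, 2))
  expect_error(read_coco18(f), "single-walker")
})

test_that("keypoint maps have the documented joint counts", {
  expect_length(keypoint_map("mediapipe33"), 16)
  expect_length(keypoint_map("coco18"), 12)
  expect_false(any(grepl("heel|foot", names(keypoint_map("coco18")))))
})

test_that("canonicalize subsets joints without touching coordinates or order", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mediapipe_fixture(f, frames = 5)
  raw <- read_mediapipe(f)
  can <- canonicalize(raw)
  expect_identical(can$dialect, "canonical16")
  expect_equal(dim(can$coords), c(5, 16, 3))
  expect_identical(can$frames, raw$frames)
  # surviving coordinates are bit-identical to the source landmarks
  map <- keypoint_map("mediapipe33")
  for (nm in names(map)) {
    expect_identical(can$coords[, nm, ],
                     raw$coords[, as.character(map[[nm]]), ])
  }
  expect_equal(attr(can, "cleaning"), list(kept = 5L, dropped = 0L))
})

test_that("low-visibility frames are dropped; >50% loss is a degraded-input error", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mediapipe_fixture(f, frames = 4)
  raw <- read_mediapipe(f)
  raw$visibility[2, 16] <- 0  # a wrist below threshold in frame 2
  can <- canonicalize(raw, min_visibility = 0.5)
  expect_equal(dim(can$coords)[1], 3)
  expect_identical(can$frames, c(0L, 2L, 3L))
  expect_equal(attr(can, "cleaning")$dropped, 1L)
  # visibility below threshold on a non-required landmark (nose) is ignored
  raw2 <- read_mediapipe(f)
  raw2$visibility[, 1] <- 0
  expect_equal(dim(canonicalize(raw2)$coords)[1], 4)

  raw3 <- read_mediapipe(f)
  raw3$visibility[1:3, 12] <- 0.1  # 75% of frames fail
  expect_error(canonicalize(raw3), "degraded")
})

test_that("canonical CSV interchange round-trips coordinates bit-exactly", {
  co <- sample_cohort(2, seed = 7, frames = 6, views = "0")
  seq <- simulate_pose_sequence(co, 1, "0", jitter_sd = 0.01)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, f)
  back <- read_pose_csv(f, subject_id = seq$subject_id, view = seq$view)
  expect_identical(back$coords, seq$coords)
  expect_identical(back$frames, seq$frames)
  expect_identical(back$dialect, "canonical16")
})

test_that("pose_sequence rejects non-increasing frame indices", {
  coords <- array(0, c(2, 16, 2), dimnames = list(NULL, names(keypoint_map("canonical16")), NULL))
  expect_error(pose_sequence(coords, frames = c(3, 3), dialect = "canonical16"),
               "strictly increasing")
})
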