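test_that("leg lengths are Euclidean distances and reject degenerate triples", {
  legs <- leg_lengths(c(0, 0), c(3, 4), c(3, 4) + c(0, 1))
  expect_equal(legs[["a"]], 5)  # 3-4-5 triangle leg
  legs2 <- leg_lengths(c(0, 1), c(0, 0), c(1, 0))
  expect_equal(unname(legs2), c(1, 1, sqrt(2)))
  expect_error(leg_lengths(c(1, 1), c(1, 1), c(0, 0)), "degenerate")
  expect_error(leg_lengths(c(0, 0, 0), c(1, 1), c(0, 0)), "dimensionality")
})

test_that("law-of-cosines angle matches the textbook cases", {
  expect_equal(joint_angle(c(a = 1, b = 1, c = sqrt(2))), 90)
  expect_equal(joint_angle(c(a = 1, b = 1, c = 2)), 180)
  expect_equal(joint_angle(c(a = 1, b = 1, c = 1)), 60)
  # derived: a=2, b=3, c=2.5 -> acos((4+9-6.25)/12)
  expect_equal(joint_angle(c(a = 2, b = 3, c = 2.5)),
               acos(6.75 / 12) * 180 / pi, tolerance = 1e-12)
})

test_that("joint_angle agrees with the vector-dot-product oracle on random triples", {
  set.seed(11)
  for (i in 1:1000) {
    d <- sample(2:3, 1)
    p <- rnorm(d); v <- rnorm(d); n <- rnorm(d)
    if (sqrt(sum((p - v)^2)) < 1e-6 || sqrt(sum((n - v)^2)) < 1e-6) next
    got <- joint_angle(leg_lengths(p, v, n))
    expect_equal(got, angle_oracle(p, v, n), tolerance = 1e-9)
  }
})

test_that("angle extraction yields the documented feature dimensions", {
  seq <- make_static_pose(frames = 3)
  ser <- extract_angle_series(seq)
  expect_equal(dim(ser$angles), c(3, 10))
  expect_identical(colnames(ser$angles),
                   c("LElbow", "RElbow", "LHip", "RHip", "LKnee", "RKnee",
                     "LAnkleFront", "RAnkleFront", "LAnkleBack", "RAnkleBack"))
  # static pose repeated -> identical rows
  expect_equal(ser$angles[1, ], ser$angles[3, ])
  expect_true(all(ser$angles >= 0 & ser$angles <= 180))

  # footless (COCO-derived) skeleton -> 6 elbow/hip/knee angles
  coco <- seq
  coco$coords <- seq$coords[, 1:12, , drop = FALSE]
  coco$dialect <- "coco18-canonical"
  ser6 <- extract_angle_series(coco)
  expect_equal(ncol(ser6$angles), 6)
  expect_identical(colnames(ser6$angles),
                   c("LElbow", "RElbow", "LHip", "RHip", "LKnee", "RKnee"))
})

test_that("body-part selection partitions the whole-body columns", {
  ser <- extract_angle_series(make_static_pose(frames = 3))
  up <- select_body_part(ser, "upper")
  lo <- select_body_part(ser, "lower")
  wh <- select_body_part(ser, "whole")
  expect_identical(colnames(up$angles), c("LElbow", "RElbow"))
  expect_equal(ncol(lo$angles), 8)
  expect_identical(colnames(wh$angles),
                   c(colnames(up$angles), colnames(lo$angles)))
  expect_length(intersect(colnames(up$angles), colnames(lo$angles)), 0)
})

test_that("COCO-18 lower body falls back to the four hip/knee angles", {
  seq <- make_static_pose(frames = 3)
  seq$coords <- seq$coords[, 1:12, , drop = FALSE]
  seq$dialect <- "coco18-canonical"
  ser <- extract_angle_series(seq)
  lo <- select_body_part(ser, "lower")
  expect_identical(colnames(lo$angles), c("LHip", "RHip", "LKnee", "RKnee"))
})

test_that("angles are invariant under rigid motion and uniform scaling", {
  set.seed(23)
  for (dims in 2:3) {
    seq <- make_static_pose(frames = 2, dims = dims)
    # deform the static pose randomly so the test is not angle-degenerate
    seq$coords <- seq$coords + array(runif(length(seq$coords), -0.02, 0.02),
                                     dim(seq$coords))
    ref <- extract_angle_series(seq)$angles
    for (i in 1:500) {
      tr <- seq
      tr$coords <- random_rigid_transform(seq$coords)
      expect_equal(extract_angle_series(tr)$angles, ref, tolerance = 1e-9)
    }
  }
})

test_that("degenerate frames are dropped with a warning", {
  seq <- make_static_pose(frames = 3)
  seq$coords[2, "elbow_l", ] <- seq$coords[2, "shoulder_l", ]  # vertex collapse
  expect_warning(ser <- extract_angle_series(seq), "degenerate")
  expect_equal(nrow(ser$angles), 2)
  expect_identical(ser$frames, c(0L, 2L))
})

test_that("3D coordinates are used when present", {
  seq2 <- make_static_pose(frames = 2, dims = 2)
  seq3 <- make_static_pose(frames = 2, dims = 3)  # distinct z per joint
  a2 <- extract_angle_series(seq2)$angles
  a3 <- extract_angle_series(seq3)$angles
  expect_false(isTRUE(all.equal(a2, a3)))
})

test_that("angle-set YAML round-trips and validates joint distinctness", {
  f <- withr::local_tempfile(fileext = ".yaml")
  def <- default_angle_set("canonical16")
  yaml::write_yaml(
    lapply(seq_len(nrow(def)), function(i) as.list(def[i, ])), f)
  back <- read_angle_set(f)
  expect_equal(back, def)

  bad <- lapply(seq_len(nrow(def)), function(i) as.list(def[i, ]))
  bad[[1]]$proximal <- bad[[1]]$vertex
  yaml::write_yaml(bad, f)
  expect_error(read_angle_set(f), "distinct")
})

test_that("angle-series CSV round-trips", {
  co <- sample_cohort(1, seed = 3, frames = 8, views = "0")
  ser <- simulate_angle_series(co, 1, "0", "reference")
  f <- withr::local_tempfile(fileext = ".csv")
  write_angle_csv(ser, f)
  back <- read_angle_csv(f, subject_id = ser$subject_id, view = ser$view)
  expect_identical(back$angles, ser$angles)
  expect_identical(back$frames, ser$frames)
})
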