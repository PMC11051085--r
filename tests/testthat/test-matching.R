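make_series <- function(mat, id, view = "0") {
  joint_angle_series(mat, subject_id = id, view = view)
}

two_col <- function(x) {
  m <- cbind(A = x, B = rev(x))
  m - min(m)  # keep within [0, 180]
}

test_that("per-view matching returns the minimum-distance identity", {
  ref <- list(make_series(two_col(c(10, 20, 30, 40)), "A"),
              make_series(two_col(c(40, 30, 20, 10) + 5), "B"))
  gal <- build_gallery(ref, "angles")
  probe <- make_series(two_col(c(11, 21, 31, 41)), "probe")
  m <- match_per_view(probe, gal, "0")
  expect_identical(m$identity, "A")
  expect_identical(names(m$distances), c("A", "B"))
  # probe identical to a gallery entry beats any positive distance
  m2 <- match_per_view(ref[[2]], gal, "0")
  expect_identical(m2$identity, "B")
  expect_equal(unname(m2$distances["B"]), 0)
  expect_error(match_per_view(probe, gal, "90"), "no entries")
})

test_that("exact argmin ties go to the smallest identity label", {
  base <- two_col(c(10, 20, 30))
  ref <- list(make_series(base, "Z"), make_series(base, "B"))
  gal <- build_gallery(ref, "angles")
  m <- match_per_view(make_series(base, "p"), gal, "0")
  expect_identical(m$identity, "B")
})

test_that("duplicate (identity, view) gallery entries are rejected", {
  ref <- list(make_series(two_col(1:3), "A"), make_series(two_col(2:4), "A"))
  expect_error(build_gallery(ref, "angles"), "duplicate")
})

test_that("majority vote is the mode, with distance-sum tie-breaking", {
  expect_identical(majority_vote(c(`0` = "A", `90` = "A", `180` = "B")), "A")
  expect_identical(majority_vote(rep("C", 11)), "C")
  # derived tie case: {A, A, B, B}, total distance A = 3.0, B = 2.5 -> B
  dists <- list(c(A = 1.0, B = 0.5), c(A = 0.5, B = 1.0),
                c(A = 0.75, B = 0.5), c(A = 0.75, B = 0.5))
  expect_identical(majority_vote(c("A", "A", "B", "B"), dists), "B")
  # without distances the smallest label wins a tied mode
  expect_identical(majority_vote(c("B", "A")), "A")
  expect_error(majority_vote(character(0)), "no per-view")
})

test_that("evaluation counts probe-view pairs and voted probes separately", {
  out <- list(
    list(true_id = "A", voted_id = "A",
         per_view = data.frame(view = c("0", "90"), matched_id = c("A", "B"))),
    list(true_id = "B", voted_id = "C",
         per_view = data.frame(view = c("0", "90"), matched_id = c("B", "B")))
  )
  rep <- evaluate_matches(out)
  expect_equal(rep$accuracy_without_voting, 3 / 4)
  expect_equal(rep$accuracy_with_voting, 1 / 2)
  expect_equal(unname(rep$per_view_accuracy), c(1, 0.5))
  expect_equal(sum(rep$confusion), 2)
})

test_that("self-matching yields exact accuracy 1.0 on every configuration", {
  co <- sample_cohort(4, seed = 61, frames = 40, views = c(0, 90),
                      view_noise_sd = 10)
  dat <- simulate_gait_data(co)
  for (f in c("angles", "correlation")) for (p in c("whole", "upper", "lower")) {
    fit <- gait_match(dat$reference, dat$reference, feature = f, part = p)
    expect_identical(fit$report$accuracy_without_voting, 1)
    expect_identical(fit$report$accuracy_with_voting, 1)
  }
})

test_that("a single view makes the voted and per-view accuracies coincide", {
  co <- sample_cohort(6, seed = 67, frames = 60, views = "90",
                      view_noise_sd = 35)
  dat <- simulate_gait_data(co)
  fit <- gait_match(dat$reference, dat$target, feature = "angles")
  expect_equal(fit$report$accuracy_with_voting,
               fit$report$accuracy_without_voting)
})

test_that("accuracy without voting equals the mean per-view accuracy", {
  co <- sample_cohort(5, seed = 71, frames = 50, views = c(0, 45, 90),
                      view_noise_sd = 30)
  dat <- simulate_gait_data(co)
  fit <- gait_match(dat$reference, dat$target, feature = "angles")
  expect_equal(fit$report$accuracy_without_voting,
               mean(fit$report$per_view_accuracy))
})

test_that("consistent identity relabeling leaves accuracies unchanged", {
  co <- sample_cohort(6, seed = 73, frames = 50, views = c(0, 90),
                      view_noise_sd = 30)
  dat <- simulate_gait_data(co)
  fit <- gait_match(dat$reference, dat$target, feature = "angles")
  perm <- setNames(sprintf("P%02d", c(3, 1, 6, 2, 5, 4)), sprintf("S%02d", 1:6))
  relabel <- function(lst) lapply(lst, function(s) {
    s$subject_id <- unname(perm[s$subject_id]); s
  })
  fit2 <- gait_match(relabel(dat$reference), relabel(dat$target),
                     feature = "angles")
  expect_equal(fit2$report$accuracy_without_voting,
               fit$report$accuracy_without_voting)
  expect_equal(fit2$report$accuracy_with_voting,
               fit$report$accuracy_with_voting)
})

test_that("probe subjects missing from the gallery are flagged and incorrect", {
  co <- sample_cohort(4, seed = 79, frames = 40, views = c(0, 90),
                      view_noise_sd = 0)
  dat <- simulate_gait_data(co)
  is_s4 <- vapply(dat$reference, function(s) s$subject_id == "S04", logical(1))
  expect_warning(
    fit <- gait_match(dat$reference[!is_s4], dat$target, feature = "angles"),
    "absent from the reference gallery")
  s4 <- Filter(function(o) o$true_id == "S04", fit$outcomes)[[1]]
  expect_false(s4$in_gallery)
  expect_false(s4$voted_id == "S04")
  expect_equal(fit$report$accuracy_with_voting, 3 / 4)
})

test_that("voting improves on single views under per-view noise (small MC)", {
  res <- sapply(1:12, function(s) {
    co <- sample_cohort(8, seed = 200 + s, frames = 60,
                        views = seq(0, 180, by = 36), view_noise_sd = 32)
    dat <- simulate_gait_data(co)
    fit <- gait_match(dat$reference, dat$target, feature = "angles")
    c(fit$report$accuracy_without_voting, fit$report$accuracy_with_voting)
  })
  expect_gt(mean(res[2, ]), mean(res[1, ]))
})

test_that("match reports are written deterministically", {
  co <- sample_cohort(3, seed = 83, frames = 40, views = c(0, 90),
                      view_noise_sd = 20)
  dat <- simulate_gait_data(co)
  fit <- gait_match(dat$reference, dat$target, feature = "correlation")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_match_report(fit, f1)
  fit_again <- gait_match(dat$reference, dat$target, feature = "correlation")
  write_match_report(fit_again, f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_length(parsed$probes, 3)
  expect_identical(parsed$config$feature, "correlation")
})
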