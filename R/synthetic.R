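# Seeded synthetic multi-subject, multi-view gait generator.
#
# Each subject walks with sinusoidal joint kinematics: angle j at frame t is
#   mean_j + amplitude_j * sin(2*pi*freq*t + phase_j) + view noise,
# with subject-specific stride frequency, per-angle means, amplitudes and
# phases (right-side angles get an extra pi by default: left/right antiphase,
# as in normal gait). Subject-specific inter-joint phase relations are what
# make both the angle time series and the Spearman correlation signature
# discriminative. The camera view enters as view-specific additive noise;
# the reference and target bouts of one subject share kinematic parameters
# but use independent noise and a random global phase offset (two separate
# walking bouts are never phase-locked).

# Per-view angle noise SD (degrees) that puts single-view matching accuracy
# near 0.6 for the default 20-subject, 11-view, 100-frame cohort — hard
# enough that individual views err often, so view aggregation has work to do.
GM_DEFAULT_NOISE_SD <- 30

#' Default parameter ranges for the synthetic gait model
#'
#' Per-angle uniform ranges for the mean posture (degrees) and the swing
#' amplitude (degrees), chosen so that mean +/- amplitude stays within
#' `[0, 180]` and resembles walking kinematics (small hip excursion about a
#' near-straight trunk-thigh angle, larger knee and elbow swings), plus the
#' stride-frequency range in cycles/frame (0.025-0.06, i.e. a gait cycle of
#' roughly 17-40 frames at surveillance frame rates).
#'
#' @return list with `freq` (length-2 range) and per-angle `mean`/`amp`
#'   ranges.
#' @export
default_gait_ranges <- function() {
  grp <- list(
    Elbow = list(mean = c(120, 160), amp = c(5, 20)),
    Hip = list(mean = c(150, 170), amp = c(3, 8)),
    Knee = list(mean = c(130, 160), amp = c(8, 18)),
    AnkleFront = list(mean = c(80, 110), amp = c(5, 15)),
    AnkleBack = list(mean = c(90, 120), amp = c(5, 15))
  )
  angles <- lapply(setNames(ANGLE_ORDER_FULL, ANGLE_ORDER_FULL), function(nm) {
    grp[[sub("^[LR]", "", nm)]]
  })
  list(freq = c(0.025, 0.06), angles = angles)
}

check_ranges <- function(ranges) {
  f <- ranges$freq
  if (f[1] <= 0 || f[2] >= 0.5 || f[1] > f[2]) {
    stop_gm("stride frequency range must lie within (0, 0.5) cycles/frame")
  }
  for (nm in names(ranges$angles)) {
    r <- ranges$angles[[nm]]
    if (r$amp[1] < 0) stop_gm("amplitude range for %s must be non-negative", nm)
    if (r$mean[2] + r$amp[2] > 180 || r$mean[1] - r$amp[2] < 0) {
      stop_gm("infeasible range for %s: mean +/- amplitude must stay in [0, 180]", nm)
    }
  }
  invisible(TRUE)
}

#' Sample a synthetic gait cohort
#'
#' Draws subject-specific gait parameters (stride frequency; per-angle mean,
#' amplitude and phase) independently from the configured ranges.
#' Deterministic for a fixed seed.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param views camera-view labels, degrees (default the 11 views 0, 18, ...,
#'   180).
#' @param frames sequence length `T` (default 100).
#' @param view_noise_sd per-view additive angle-noise SD in degrees; a scalar
#'   is recycled over views. Default: the calibrated
#'   moderately-hard-matching value (see the methods vignette).
#' @param seed RNG seed.
#' @param ranges parameter ranges, as from [default_gait_ranges()].
#' @param antiphase add pi to right-side phases (left/right limbs in
#'   antiphase, the normal gait symmetry). Default `TRUE`.
#' @return object of class `gait_cohort`: list with `subjects` (per-subject
#'   parameter lists), `views`, `frames`, `view_noise_sd` (named per view),
#'   `seed`.
#' @export
sample_cohort <- function(n_subjects, views = seq(0, 180, by = 18),
                          frames = 100, view_noise_sd = GM_DEFAULT_NOISE_SD,
                          seed = 1, ranges = default_gait_ranges(),
                          antiphase = TRUE) {
  if (n_subjects < 1) stop_gm("need at least one subject")
  if (frames < 2) stop_gm("need at least 2 frames")
  if (any(view_noise_sd < 0)) stop_gm("view_noise_sd must be non-negative")
  check_ranges(ranges)
  views <- as.character(views)
  if (anyDuplicated(views)) stop_gm("view labels must be unique")
  if (length(view_noise_sd) == 1) view_noise_sd <- rep(view_noise_sd, length(views))
  if (length(view_noise_sd) != length(views)) {
    stop_gm("view_noise_sd must be scalar or one value per view")
  }
  names(view_noise_sd) <- views

  angle_names <- names(ranges$angles)
  subjects <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      ph <- runif(length(angle_names), 0, 2 * pi)
      if (antiphase) ph <- ph + ifelse(grepl("^R", angle_names), pi, 0)
      list(
        id = sprintf("S%02d", i),
        freq = runif(1, ranges$freq[1], ranges$freq[2]),
        mean = vapply(ranges$angles, function(r) runif(1, r$mean[1], r$mean[2]),
                      numeric(1)),
        amp = vapply(ranges$angles, function(r) runif(1, r$amp[1], r$amp[2]),
                     numeric(1)),
        phase = setNames(ph, angle_names)
      )
    })
  })
  structure(
    list(subjects = subjects, views = views, frames = frames,
         view_noise_sd = view_noise_sd, seed = seed,
         angle_names = angle_names),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %d views, T=%d, noise SD %s deg, seed %d\n",
              length(x$subjects), length(x$views), x$frames,
              paste(format(unique(unname(x$view_noise_sd))), collapse = "/"),
              x$seed))
  invisible(x)
}

# Deterministic angle trajectory (no noise, no bout offset).
angle_trajectory <- function(subject, frames, phase_offset = 0) {
  t <- seq_len(frames) - 1
  sapply(seq_along(subject$mean), function(j) {
    subject$mean[j] + subject$amp[j] *
      sin(2 * pi * subject$freq * t + subject$phase[j] + phase_offset)
  })
}

#' Simulate one joint-angle sequence for a subject in one view
#'
#' Sinusoidal subject kinematics plus `N(0, sd^2)` view noise, clipped to
#' `[0, 180]`. A `"target"` bout is a random circular frame shift of the
#' subject's periodic trajectory (all angles shifted together, with
#' wraparound) — an independent walking bout of the same person picked up at
#' an arbitrary point of the gait cycle — with its own noise draw; a
#' `"reference"` bout starts at shift 0. The circular shift permutes frames
#' jointly across angle columns, so rank-correlation features of two
#' noiseless bouts are identical while the angle time series themselves are
#' misaligned in time.
#'
#' @param cohort a [sample_cohort()] object.
#' @param subject_idx subject index within the cohort.
#' @param view view label (must be one of the cohort's views).
#' @param role `"reference"` or `"target"`.
#' @param seed RNG seed for this sequence's noise and bout shift; defaults
#'   to a child seed derived from the cohort seed and the
#'   (subject, view, role) triple.
#' @param bout_shift override the circular bout shift (frames); `NULL`
#'   means role-determined (0 for reference, uniform on `0..T-1` for
#'   target).
#' @return a [joint_angle_series()] with `T x 10` angles.
#' @export
simulate_angle_series <- function(cohort, subject_idx, view,
                                  role = c("reference", "target"),
                                  seed = NULL, bout_shift = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(cohort, "gait_cohort"))
  view <- as.character(view)
  if (!view %in% cohort$views) stop_gm("unknown view '%s'", view)
  subject <- cohort$subjects[[subject_idx]]
  vi <- match(view, cohort$views)
  if (is.null(seed)) {
    seed <- child_seed(cohort$seed, subject_idx, vi,
                       if (role == "reference") 1L else 2L)
  }
  sd_v <- cohort$view_noise_sd[[view]]
  tt <- cohort$frames
  with_seed(seed, {
    s <- bout_shift %||% if (role == "reference") 0L else sample.int(tt, 1) - 1L
    ang <- angle_trajectory(subject, tt)
    if (s %% tt != 0) {
      idx <- ((seq_len(tt) - 1 + s) %% tt) + 1
      ang <- ang[idx, , drop = FALSE]
    }
    if (sd_v > 0) ang <- ang + matrix(rnorm(length(ang), 0, sd_v), nrow(ang))
    ang <- pmin(pmax(ang, 0), 180)  # argument order keeps the dim attribute
    colnames(ang) <- cohort$angle_names
    joint_angle_series(ang, subject_id = subject$id, view = view)
  })
}

#' Simulate a full reference + target dataset from a cohort
#'
#' One reference and one target sequence per subject per view.
#'
#' @param cohort a [sample_cohort()] object.
#' @param target_bout_shift optional fixed circular bout shift (frames) for
#'   all targets (`NULL` = random per target).
#' @return list with `reference` and `target`: lists of
#'   [joint_angle_series()].
#' @export
simulate_gait_data <- function(cohort, target_bout_shift = NULL) {
  stopifnot(inherits(cohort, "gait_cohort"))
  grid <- expand.grid(si = seq_along(cohort$subjects), view = cohort$views,
                      stringsAsFactors = FALSE)
  reference <- mapply(function(si, v) {
    simulate_angle_series(cohort, si, v, "reference")
  }, grid$si, grid$view, SIMPLIFY = FALSE)
  target <- mapply(function(si, v) {
    simulate_angle_series(cohort, si, v, "target",
                          bout_shift = target_bout_shift)
  }, grid$si, grid$view, SIMPLIFY = FALSE)
  list(reference = reference, target = target)
}

# Planar rotation of row vectors by `deg` degrees.
rot2 <- function(v, deg) {
  th <- deg * pi / 180
  cbind(cos(th) * v[, 1] - sin(th) * v[, 2],
        sin(th) * v[, 1] + cos(th) * v[, 2])
}

# Segment lengths (arbitrary units) for the planar kinematic chain.
CHAIN <- list(
  torso = 0.5, shoulder_w = 0.35, upper_arm = 0.30, forearm = 0.27,
  thigh = 0.45, shank = 0.45, foot = 0.20, heel = 0.08, stride = 0.01
)

#' Simulate a canonical-16 pose sequence for a subject in one view
#'
#' Embeds the subject's deterministic angle trajectories in a planar
#' kinematic chain with fixed segment lengths: shoulders and hips are fixed
#' in the body frame (translated forward at a constant walking speed), and
#' each limb joint is placed so that the interior angle at the vertex equals
#' the generating angle exactly. With zero landmark jitter,
#' [extract_angle_series()] on the output recovers the generating angles to
#' well below 1e-6 degrees; Gaussian jitter of SD `jitter_sd` (coordinate
#' units) perturbs every landmark coordinate independently.
#'
#' @inheritParams simulate_angle_series
#' @param jitter_sd landmark noise SD in coordinate units (default 0).
#' @return a [pose_sequence()] in the `canonical16` dialect, with the
#'   generating `T x 10` angle matrix attached as attribute `"angles"`.
#' @export
simulate_pose_sequence <- function(cohort, subject_idx, view, seed = NULL,
                                   jitter_sd = 0) {
  stopifnot(inherits(cohort, "gait_cohort"))
  view <- as.character(view)
  if (!view %in% cohort$views) stop_gm("unknown view '%s'", view)
  subject <- cohort$subjects[[subject_idx]]
  if (is.null(seed)) {
    seed <- child_seed(cohort$seed, subject_idx, match(view, cohort$views), 3L)
  }
  tt <- cohort$frames
  ang <- angle_trajectory(subject, tt)
  colnames(ang) <- cohort$angle_names

  walk_x <- CHAIN$stride * (seq_len(tt) - 1)
  coords <- array(NA_real_, c(tt, 16L, 2L),
                  dimnames = list(NULL, CANONICAL16, c("x", "y")))
  place_side <- function(side) {
    sx <- if (side == "l") 0 else CHAIN$shoulder_w
    S <- cbind(walk_x + sx, rep(0, tt))            # shoulder
    H <- cbind(S[, 1], S[, 2] - CHAIN$torso)       # hip
    E <- cbind(S[, 1], S[, 2] - CHAIN$upper_arm)   # elbow hangs straight down
    pick <- function(stub) ang[, paste0(toupper(side), stub)]
    unit <- function(from, to) (to - from) / sqrt(rowSums((to - from)^2))
    W <- E + CHAIN$forearm * rot2(unit(E, S), pick("Elbow"))
    K <- H + CHAIN$thigh * rot2(unit(H, S), pick("Hip"))
    A <- K + CHAIN$shank * rot2(unit(K, H), pick("Knee"))
    FT <- A + CHAIN$foot * rot2(unit(A, K), pick("AnkleFront"))
    HL <- A + CHAIN$heel * rot2(unit(A, K), pick("AnkleBack"))
    list(shoulder = S, elbow = E, wrist = W, hip = H, knee = K, ankle = A,
         heel = HL, foot_index = FT)
  }
  for (side in c("l", "r")) {
    pts <- place_side(side)
    for (nm in names(pts)) {
      coords[, paste0(if (nm == "foot_index") "foot_index" else nm, "_", side), ] <-
        pts[[nm]]
    }
  }
  if (jitter_sd > 0) {
    coords <- coords + with_seed(seed, array(rnorm(length(coords), 0, jitter_sd),
                                             dim(coords)))
  }
  out <- pose_sequence(coords, dialect = "canonical16",
                       subject_id = subject$id, view = view,
                       visibility = matrix(1, tt, 16L))
  attr(out, "angles") <- ang
  out
}

#' Write a simulated dataset to a reference/target directory layout
#'
#' Creates `reference/` and `target/` subdirectories with one angle CSV per
#' (subject, view): `<subject>_view<view>.csv`.
#'
#' @param dat a [simulate_gait_data()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dat, dir) {
  for (role in c("reference", "target")) {
    sub <- file.path(dir, role)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    for (s in dat[[role]]) {
      write_angle_csv(s, file.path(sub, sprintf("%s_view%s.csv",
                                                s$subject_id, s$view)))
    }
  }
  invisible(dir)
}

#' Read a reference/target angle-CSV dataset written by [write_gait_dataset()]
#'
#' @param dir dataset directory containing `reference/` and `target/`.
#' @return list with `reference` and `target` lists of
#'   [joint_angle_series()].
#' @export
read_gait_dataset <- function(dir) {
  list(reference = read_angle_dir(file.path(dir, "reference")),
       target = read_angle_dir(file.path(dir, "target")))
}

#' Read a flat directory of `<subject>_view<view>.csv` angle files
#'
#' @param dir directory of angle CSVs named as written by
#'   [write_gait_dataset()].
#' @return list of [joint_angle_series()].
#' @export
read_angle_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop_gm("no CSV files under %s", dir)
  lapply(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^(.*)_view([^.]*)\\.csv$", basename(f)))[[1]]
    if (length(m) != 3) stop_gm("cannot parse subject/view from %s", basename(f))
    read_angle_csv(f, subject_id = m[2], view = m[3])
  })
}
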