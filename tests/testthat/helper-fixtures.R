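# Shared fixtures, built in code.

# Tiny canonical-16 pose sequence: a static standing pose repeated T times,
# optionally with per-frame forward translation.
make_static_pose <- function(frames = 4, translate = 0, dims = 2,
                             visibility = NULL) {
  base <- rbind(
    shoulder_l = c(0.0, 1.6), shoulder_r = c(0.35, 1.6),
    elbow_l = c(-0.05, 1.30), elbow_r = c(0.40, 1.30),
    wrist_l = c(-0.10, 1.05), wrist_r = c(0.45, 1.05),
    hip_l = c(0.05, 1.05), hip_r = c(0.30, 1.05),
    knee_l = c(0.02, 0.60), knee_r = c(0.33, 0.60),
    ankle_l = c(0.00, 0.15), ankle_r = c(0.35, 0.15),
    heel_l = c(-0.05, 0.10), heel_r = c(0.30, 0.10),
    foot_index_l = c(0.12, 0.05), foot_index_r = c(0.47, 0.05)
  )
  coords <- array(NA_real_, c(frames, 16, dims),
                  dimnames = list(NULL, rownames(base),
                                  c("x", "y", "z")[seq_len(dims)]))
  for (t in seq_len(frames)) {
    coords[t, , 1] <- base[, 1] + translate * (t - 1)
    coords[t, , 2] <- base[, 2]
    if (dims == 3) coords[t, , 3] <- 0.1 * seq_len(16)
  }
  pose_sequence(coords, dialect = "canonical16", subject_id = "fix",
                view = "0", visibility = visibility)
}

# A MediaPipe-style long CSV with all 33 landmarks per frame.
write_mediapipe_fixture <- function(path, frames = 3, drop_landmark = NULL,
                                    visibility = 1) {
  rows <- do.call(rbind, lapply(seq_len(frames) - 1L, function(t) {
    lm <- 0:32
    if (!is.null(drop_landmark) && t == 1) lm <- setdiff(lm, drop_landmark)
    data.frame(frame = t, landmark = lm,
               x = lm / 33 + t, y = sin(lm + t), z = cos(lm + t),
               visibility = visibility)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# An OpenPose-style JSON fixture: list of frames, each with `people`.
write_coco_fixture <- function(path, n_people = c(1, 1, 1)) {
  frames <- lapply(seq_along(n_people), function(t) {
    people <- lapply(seq_len(n_people[t]), function(p) {
      kp <- as.vector(rbind(seq_len(18) / 18 + t, sin(seq_len(18) + t), 0.9))
      list(pose_keypoints_2d = kp)
    })
    list(frame = t - 1L, people = people)
  })
  jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA)
  path
}

# Independent DTW oracle: exhaustive minimization over every monotone,
# continuous warping path (plain recursion, no DP reuse of the tested code).
dtw_brute <- function(a, b) {
  la <- length(a); lb <- length(b)
  rec <- function(u, v) {
    lc <- abs(a[u] - b[v])
    if (u == 1 && v == 1) return(lc)
    best <- Inf
    if (u > 1 && v > 1) best <- min(best, rec(u - 1, v - 1))
    if (u > 1) best <- min(best, rec(u - 1, v))
    if (v > 1) best <- min(best, rec(u, v - 1))
    lc + best
  }
  rec(la, lb)
}

# Independent joint-angle oracle: angle between the two segment vectors via
# the normalized dot product.
angle_oracle <- function(p_prev, p_vertex, p_next) {
  u <- p_prev - p_vertex
  v <- p_next - p_vertex
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Random rigid motion + uniform scaling applied to a T x J x D coord array.
random_rigid_transform <- function(coords) {
  d <- dim(coords)[3]
  if (d == 2) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  } else {
    M <- matrix(rnorm(9), 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
  }
  s <- runif(1, 0.2, 5)
  shift <- runif(d, -10, 10)
  out <- coords
  flat <- matrix(coords, ncol = d)
  flat <- s * (flat %*% t(R))
  flat <- sweep(flat, 2, shift, "+")
  array(flat, dim(coords), dimnames(coords))
}
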