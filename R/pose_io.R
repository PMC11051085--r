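# Readers and writers for pose-estimation output formats.

#' Read a MediaPipe 33-landmark pose sequence
#'
#' Accepts either JSON-lines (one record per frame:
#' `{"frame": t, "landmarks": [[x, y, z, visibility] x 33]}`, landmark objects
#' `{"x": ..., "y": ..., "z": ..., "visibility": ...}` also accepted) or a
#' long CSV with columns `frame,landmark,x,y,z[,visibility]` where `landmark`
#' is the 0-based MediaPipe index. No coordinate transformation is applied;
#' frame order is preserved.
#'
#' @param path file path.
#' @param subject_id,view optional labels attached to the sequence.
#' @return a [pose_sequence()] in the `mediapipe33` dialect.
#' @export
read_mediapipe <- function(path, subject_id = NA, view = NA) {
  if (grepl("\\.(json|jsonl)$", path, ignore.case = TRUE)) {
    read_mediapipe_jsonl(path, subject_id, view)
  } else {
    read_mediapipe_csv(path, subject_id, view)
  }
}

read_mediapipe_jsonl <- function(path, subject_id, view) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_gm("empty MediaPipe input: %s", path)
  tt <- length(lines)
  coords <- array(NA_real_, c(tt, 33L, 3L),
                  dimnames = list(NULL, as.character(0:32), c("x", "y", "z")))
  vis <- matrix(1, tt, 33L)
  frames <- integer(tt)
  for (t in seq_len(tt)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[t], simplifyMatrix = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$landmarks)) {
      stop_gm("malformed MediaPipe record at frame line %d of %s", t, path)
    }
    lm <- rec$landmarks
    if (is.data.frame(lm)) {
      if (!all(c("x", "y", "z") %in% names(lm))) {
        stop_gm("malformed MediaPipe record at frame line %d: landmarks lack x/y/z", t)
      }
      m <- cbind(lm$x, lm$y, lm$z)
      v <- if ("visibility" %in% names(lm)) lm$visibility else rep(1, nrow(lm))
    } else {
      lm <- as.matrix(lm)
      if (ncol(lm) < 3L) stop_gm("malformed MediaPipe record at frame line %d", t)
      m <- lm[, 1:3, drop = FALSE]
      v <- if (ncol(lm) >= 4L) lm[, 4] else rep(1, nrow(lm))
    }
    if (nrow(m) != 33L) {
      stop_gm("frame line %d of %s has %d landmarks (expected 33)", t, path, nrow(m))
    }
    coords[t, , ] <- m
    vis[t, ] <- v
    frames[t] <- if (!is.null(rec$frame)) as.integer(rec$frame) else t - 1L
  }
  pose_sequence(coords, frames, "mediapipe33", subject_id, view, vis)
}

read_mediapipe_csv <- function(path, subject_id, view) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop_gm("empty MediaPipe input: %s", path)
  need <- c("frame", "landmark", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_gm("MediaPipe CSV must have columns %s", paste(need, collapse = ","))
  }
  frames <- sort(unique(df$frame))
  tt <- length(frames)
  coords <- array(NA_real_, c(tt, 33L, 3L),
                  dimnames = list(NULL, as.character(0:32), c("x", "y", "z")))
  vis <- matrix(1, tt, 33L)
  for (t in seq_len(tt)) {
    sub <- df[df$frame == frames[t], , drop = FALSE]
    idx <- match(0:32, sub$landmark)
    if (anyNA(idx)) {
      stop_gm("frame %s of %s is missing landmark(s): %s", frames[t], path,
              paste((0:32)[is.na(idx)], collapse = ", "))
    }
    coords[t, , ] <- as.matrix(sub[idx, c("x", "y", "z")])
    if ("visibility" %in% names(sub)) vis[t, ] <- sub$visibility[idx]
  }
  pose_sequence(coords, as.integer(frames), "mediapipe33", subject_id, view, vis)
}

#' Read an OpenPose/AlphaPose COCO-18 pose sequence
#'
#' Expects a JSON array of frame records, each
#' `{"frame": t, "people": [{"pose_keypoints_2d": [54 floats]}]}` (the
#' standard OpenPose layout: 18 keypoints as x, y, confidence triplets).
#' Confidence is stored as visibility; no z axis exists in this dialect.
#' The matcher assumes a single walker: a frame with more than one person is
#' an error, and a frame with none is dropped with a warning.
#'
#' @inheritParams read_mediapipe
#' @return a [pose_sequence()] in the `coco18` dialect.
#' @export
read_coco18 <- function(path, subject_id = NA, view = NA) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) stop_gm("empty COCO-18 input: %s", path)
  coords_l <- list(); vis_l <- list(); frames <- integer(0)
  for (t in seq_along(recs)) {
    rec <- recs[[t]]
    people <- rec$people
    if (is.null(people) || length(people) == 0) {
      warning(sprintf("frame %d of %s has no person; dropped", t, basename(path)),
              call. = FALSE)
      next
    }
    if (length(people) > 1) {
      stop_gm("frame %d of %s has %d people; single-walker sequences only",
              t, path, length(people))
    }
    kp <- unlist(people[[1]]$pose_keypoints_2d)
    if (length(kp) != 54) {
      stop_gm("frame %d of %s: pose_keypoints_2d has %d values (expected 54)",
              t, path, length(kp))
    }
    m <- matrix(kp, ncol = 3, byrow = TRUE)
    coords_l[[length(coords_l) + 1L]] <- m[, 1:2]
    vis_l[[length(vis_l) + 1L]] <- m[, 3]
    frames <- c(frames, if (!is.null(rec$frame)) as.integer(rec$frame) else t - 1L)
  }
  if (length(coords_l) == 0) stop_gm("no usable frames in %s", path)
  tt <- length(coords_l)
  coords <- array(NA_real_, c(tt, 18L, 2L),
                  dimnames = list(NULL, as.character(0:17), c("x", "y")))
  vis <- matrix(1, tt, 18L)
  for (t in seq_len(tt)) {
    coords[t, , ] <- coords_l[[t]]
    vis[t, ] <- vis_l[[t]]
  }
  pose_sequence(coords, frames, "coco18", subject_id, view, vis)
}

#' Read / write the canonical long-CSV pose interchange format
#'
#' Columns `frame,joint,x,y[,z][,visibility]` with canonical joint names.
#' `write_pose_csv` prints coordinates at full double precision so that a
#' write/read round trip is bit-exact.
#'
#' @param path file path.
#' @param subject_id,view optional labels.
#' @return `read_pose_csv`: a [pose_sequence()] in the `canonical16` (16
#'   joints) or `coco18-canonical` (12 joints) dialect.
#' @export
read_pose_csv <- function(path, subject_id = NA, view = NA) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop_gm("empty pose CSV: %s", path)
  if (!all(c("frame", "joint", "x", "y") %in% names(df))) {
    stop_gm("pose CSV must have columns frame,joint,x,y")
  }
  joints <- unique(df$joint)
  dialect <- if (setequal(joints, CANONICAL16)) "canonical16"
    else if (setequal(joints, CANONICAL12)) "coco18-canonical"
    else stop_gm("pose CSV joints are not a canonical set (got %d names)", length(joints))
  jset <- if (dialect == "canonical16") CANONICAL16 else CANONICAL12
  has_z <- "z" %in% names(df) && !all(is.na(df$z))
  frames <- sort(unique(df$frame))
  tt <- length(frames); nj <- length(jset); nd <- if (has_z) 3L else 2L
  coords <- array(NA_real_, c(tt, nj, nd),
                  dimnames = list(NULL, jset, c("x", "y", "z")[seq_len(nd)]))
  vis <- if ("visibility" %in% names(df)) matrix(1, tt, nj) else NULL
  for (t in seq_len(tt)) {
    sub <- df[df$frame == frames[t], , drop = FALSE]
    idx <- match(jset, sub$joint)
    if (anyNA(idx)) {
      stop_gm("frame %s of %s is missing joint(s): %s", frames[t], path,
              paste(jset[is.na(idx)], collapse = ", "))
    }
    coords[t, , 1] <- sub$x[idx]
    coords[t, , 2] <- sub$y[idx]
    if (has_z) coords[t, , 3] <- sub$z[idx]
    if (!is.null(vis)) vis[t, ] <- sub$visibility[idx]
  }
  pose_sequence(coords, as.integer(frames), dialect, subject_id, view, vis)
}

#' @param seq a canonical [pose_sequence()] to write.
#' @rdname read_pose_csv
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!seq$dialect %in% c("canonical16", "coco18-canonical")) {
    stop_gm("write_pose_csv expects a canonical sequence; canonicalize() first")
  }
  jn <- joint_names(seq)
  tt <- n_frames(seq)
  has_z <- dim(seq$coords)[3] >= 3L
  rows <- character(0)
  header <- paste(c("frame", "joint", "x", "y", if (has_z) "z",
                    if (!is.null(seq$visibility)) "visibility"), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  for (t in seq_len(tt)) {
    for (j in seq_along(jn)) {
      fields <- c(seq$frames[t], jn[j],
                  fmt_num(seq$coords[t, j, 1]), fmt_num(seq$coords[t, j, 2]),
                  if (has_z) fmt_num(seq$coords[t, j, 3]),
                  if (!is.null(seq$visibility)) fmt_num(seq$visibility[t, j]))
      rows <- c(rows, paste(fields, collapse = ","))
    }
  }
  writeLines(rows, con)
  invisible(path)
}
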