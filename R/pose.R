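# Pose-sequence container, skeleton dialects and keypoint maps.

# Canonical joint names, left/right pairs. The 16-joint set is the minimal
# MediaPipe subset supporting all ten elbow/hip/knee/ankle angles; the
# 12-joint set is what COCO-18 skeletons can supply (no foot landmarks, so
# no ankle angles).
CANONICAL16 <- c(
  "shoulder_l", "shoulder_r", "elbow_l", "elbow_r", "wrist_l", "wrist_r",
  "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r",
  "heel_l", "heel_r", "foot_index_l", "foot_index_r"
)
CANONICAL12 <- CANONICAL16[1:12]

# MediaPipe BlazePose landmark indices (0-based) for the canonical joints.
MEDIAPIPE33_MAP <- c(
  shoulder_l = 11L, shoulder_r = 12L, elbow_l = 13L, elbow_r = 14L,
  wrist_l = 15L, wrist_r = 16L, hip_l = 23L, hip_r = 24L,
  knee_l = 25L, knee_r = 26L, ankle_l = 27L, ankle_r = 28L,
  heel_l = 29L, heel_r = 30L, foot_index_l = 31L, foot_index_r = 32L
)

# OpenPose/AlphaPose BODY-18 indices (0-based); no heel / foot_index.
COCO18_MAP <- c(
  shoulder_l = 5L, shoulder_r = 2L, elbow_l = 6L, elbow_r = 3L,
  wrist_l = 7L, wrist_r = 4L, hip_l = 11L, hip_r = 8L,
  knee_l = 12L, knee_r = 9L, ankle_l = 13L, ankle_r = 10L
)

#' Keypoint map for a skeleton dialect
#'
#' Maps a pose-estimation dialect's joint indices to the canonical joint names
#' used by the angle definitions. The MediaPipe map has 16 entries (shoulders,
#' elbows, wrists, hips, knees, ankles, heels, foot indices, left and right);
#' the COCO-18 map has 12 (no foot landmarks exist in that skeleton).
#'
#' @param dialect one of `"mediapipe33"`, `"coco18"`, `"canonical16"`,
#'   `"coco18-canonical"`.
#' @return object of class `keypoint_map`: a named vector (canonical joint
#'   name -> 0-based source landmark index, or the identity name map for
#'   already-canonical dialects) with a `dialect` attribute.
#' @examples
#' length(keypoint_map("mediapipe33"))  # 16
#' length(keypoint_map("coco18"))       # 12
#' @export
keypoint_map <- function(dialect = c("mediapipe33", "coco18", "canonical16",
                                     "coco18-canonical")) {
  dialect <- match.arg(dialect)
  m <- switch(dialect,
    mediapipe33 = MEDIAPIPE33_MAP,
    coco18 = COCO18_MAP,
    canonical16 = setNames(CANONICAL16, CANONICAL16),       # identity map
    `coco18-canonical` = setNames(CANONICAL12, CANONICAL12)
  )
  structure(m, dialect = dialect, class = "keypoint_map")
}

#' Construct a pose sequence
#'
#' The canonical in-memory representation of one person's landmark time series
#' in one camera view: a `T x J x D` coordinate array (frames x joints x
#' axes), optional per-landmark visibility, frame indices, and the skeleton
#' dialect the joint dimension is expressed in.
#'
#' @param coords numeric array `T x J x D` (`D` = 2 or 3) with joint names as
#'   `dimnames[[2]]`.
#' @param frames integer frame indices, strictly increasing; defaults to
#'   `0:(T-1)`.
#' @param dialect skeleton dialect string.
#' @param subject_id,view optional identity label and camera-view label
#'   (degrees).
#' @param visibility optional `T x J` matrix in `[0, 1]`.
#' @return object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, frames = NULL, dialect, subject_id = NA,
                          view = NA, visibility = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  tt <- dim(coords)[1]
  if (is.null(frames)) frames <- seq_len(tt) - 1L
  frames <- as.integer(frames)
  if (length(frames) != tt) stop_gm("frames length (%d) != T (%d)", length(frames), tt)
  if (tt > 1 && any(diff(frames) <= 0)) stop_gm("frame indices must be strictly increasing")
  if (!is.null(visibility)) {
    visibility <- as.matrix(visibility)
    if (!all(dim(visibility) == dim(coords)[1:2])) {
      stop_gm("visibility must be T x J")
    }
  }
  structure(
    list(coords = coords, frames = frames, dialect = dialect,
         subject_id = subject_id, view = view, visibility = visibility),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<pose_sequence> %s | subject=%s view=%s | T=%d frames, %d joints, %dD\n",
              x$dialect, as.character(x$subject_id), as.character(x$view),
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.pose_sequence <- function(x) dim(x$coords)

n_frames <- function(seq) dim(seq$coords)[1]

joint_names <- function(seq) dimnames(seq$coords)[[2]]

# T x D coordinate slab for one joint, never dropped to a vector.
joint_xy <- function(seq, joint) {
  d <- dim(seq$coords)
  matrix(seq$coords[, joint, , drop = FALSE], nrow = d[1], ncol = d[3])
}

#' Subset a pose sequence to canonical keypoints and clean low-visibility frames
#'
#' Keeps only the keypoints named by `map` (renaming them to canonical joint
#' names), drops every frame in which any required keypoint falls below the
#' visibility threshold, and refuses to proceed if more than half of the
#' frames are lost (matching at that level of degradation is untrustworthy).
#' Surviving frames keep their order and their coordinates untouched. The
#' cleaning report is attached as attribute `"cleaning"` (`kept`, `dropped`).
#'
#' @param seq a [pose_sequence()].
#' @param map a [keypoint_map()]; must match `seq`'s dialect. Defaults to the
#'   map for `seq$dialect`.
#' @param min_visibility frames where any required keypoint's visibility is
#'   below this are dropped (default 0.5). Ignored when the sequence carries
#'   no visibility channel.
#' @return a `pose_sequence` in the `canonical16` dialect (or
#'   `coco18-canonical`, 12 joints, for foot-less skeletons).
#' @export
canonicalize <- function(seq, map = keypoint_map(seq$dialect),
                         min_visibility = 0.5) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!identical(attr(map, "dialect"), seq$dialect)) {
    stop_gm("keypoint map dialect '%s' does not match sequence dialect '%s'",
            attr(map, "dialect"), seq$dialect)
  }
  jn <- joint_names(seq)
  src_idx <- match(as.character(unclass(map)), jn)
  if (anyNA(src_idx)) {
    stop_gm("sequence is missing required landmarks: %s",
            paste(names(map)[is.na(src_idx)], collapse = ", "))
  }
  coords <- seq$coords[, src_idx, , drop = FALSE]
  dimnames(coords)[[2]] <- names(map)
  vis <- if (is.null(seq$visibility)) NULL else seq$visibility[, src_idx, drop = FALSE]

  tt <- dim(coords)[1]
  keep <- rep(TRUE, tt)
  if (!is.null(vis)) keep <- apply(vis >= min_visibility, 1L, all)
  n_drop <- sum(!keep)
  if (n_drop > 0 && n_drop > tt / 2) {
    stop_gm("degraded input: %d of %d frames fail the visibility threshold (> 50%%)",
            n_drop, tt)
  }
  out_dialect <- if (length(map) == 16L) "canonical16" else "coco18-canonical"
  out <- pose_sequence(
    coords[keep, , , drop = FALSE], frames = seq$frames[keep],
    dialect = out_dialect, subject_id = seq$subject_id, view = seq$view,
    visibility = if (is.null(vis)) NULL else vis[keep, , drop = FALSE]
  )
  attr(out, "cleaning") <- list(kept = sum(keep), dropped = n_drop)
  out
}
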