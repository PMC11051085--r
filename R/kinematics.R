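# Joint-angle extraction: Euclidean leg lengths + law of cosines.

# Fixed column order for the ten-angle whole-body feature vector.
ANGLE_ORDER_FULL <- c("LElbow", "RElbow", "LHip", "RHip", "LKnee", "RKnee",
                      "LAnkleFront", "RAnkleFront", "LAnkleBack", "RAnkleBack")
ANGLE_ORDER_COCO <- ANGLE_ORDER_FULL[1:6]
UPPER_ANGLES <- c("LElbow", "RElbow")

#' Default joint-angle definitions
#'
#' Each angle is the interior angle at a vertex joint between the segments to
#' a proximal and a distal joint: elbow = shoulder-elbow-wrist, hip =
#' shoulder-hip-knee, knee = hip-knee-ankle, ankle(front) =
#' knee-ankle-foot_index, ankle(back) = knee-ankle-heel, on both body sides.
#' The full set has 10 angles; skeletons without foot landmarks (COCO-18)
#' support only the 6 elbow/hip/knee angles.
#'
#' @param dialect `"canonical16"` (10 angles) or `"coco18-canonical"`
#'   (6 angles).
#' @return data frame with columns `name`, `proximal`, `vertex`, `distal`,
#'   `body_part` (`upper` or `lower`), in the fixed feature-column order.
#' @export
default_angle_set <- function(dialect = c("canonical16", "coco18-canonical")) {
  dialect <- match.arg(dialect)
  def <- data.frame(
    name = ANGLE_ORDER_FULL,
    proximal = c("shoulder_l", "shoulder_r", "shoulder_l", "shoulder_r",
                 "hip_l", "hip_r", "knee_l", "knee_r", "knee_l", "knee_r"),
    vertex = c("elbow_l", "elbow_r", "hip_l", "hip_r", "knee_l", "knee_r",
               "ankle_l", "ankle_r", "ankle_l", "ankle_r"),
    distal = c("wrist_l", "wrist_r", "knee_l", "knee_r", "ankle_l", "ankle_r",
               "foot_index_l", "foot_index_r", "heel_l", "heel_r"),
    body_part = c("upper", "upper", rep("lower", 8)),
    stringsAsFactors = FALSE
  )
  if (dialect == "coco18-canonical") def <- def[1:6, ]
  def
}

#' Read an angle-set definition from YAML
#'
#' The file is a list of entries with fields `name`, `proximal`, `vertex`,
#' `distal`, `body_part`.
#'
#' @param path YAML file path.
#' @return data frame in the same layout as [default_angle_set()].
#' @export
read_angle_set <- function(path) {
  lst <- yaml::read_yaml(path)
  def <- do.call(rbind, lapply(lst, function(e) {
    data.frame(name = e$name, proximal = e$proximal, vertex = e$vertex,
               distal = e$distal, body_part = e$body_part,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(def$name)) stop_gm("duplicate angle names in %s", path)
  bad <- def$proximal == def$vertex | def$distal == def$vertex |
    def$proximal == def$distal
  if (any(bad)) stop_gm("angle(s) with non-distinct joints: %s",
                        paste(def$name[bad], collapse = ", "))
  def
}

#' Triangle leg lengths for three landmarks
#'
#' Euclidean distances forming the triangle whose middle angle is the joint
#' angle: `a` from vertex to proximal, `b` from vertex to distal, `c` across
#' from proximal to distal. Points may be 2D or 3D (matching dimensionality).
#'
#' @param p_prev,p_vertex,p_next numeric coordinate vectors.
#' @return named numeric vector `c(a=, b=, c=)`.
#' @export
leg_lengths <- function(p_prev, p_vertex, p_next) {
  if (length(p_prev) != length(p_vertex) || length(p_next) != length(p_vertex)) {
    stop_gm("points must share dimensionality")
  }
  a <- sqrt(sum((p_vertex - p_prev)^2))
  b <- sqrt(sum((p_vertex - p_next)^2))
  cc <- sqrt(sum((p_prev - p_next)^2))
  if (a == 0 || b == 0) {
    stop_gm("degenerate triangle: vertex coincides with an endpoint")
  }
  c(a = a, b = b, c = cc)
}

#' Joint angle from triangle legs (law of cosines)
#'
#' `theta = acos((a^2 + b^2 - c^2) / (2ab))` in degrees, with the acos
#' argument clamped to `[-1, 1]` to absorb floating-point excursions. Always
#' in `[0, 180]`.
#'
#' @param legs named vector with elements `a`, `b`, `c` (see [leg_lengths()]).
#' @return angle in degrees.
#' @examples
#' joint_angle(c(a = 1, b = 1, c = sqrt(2)))  # 90
#' @export
joint_angle <- function(legs) {
  a <- legs[["a"]]; b <- legs[["b"]]; cc <- legs[["c"]]
  if (a <= 0 || b <= 0) stop_gm("leg lengths a, b must be positive")
  arg <- (a^2 + b^2 - cc^2) / (2 * a * b)
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' Joint-angle time series from a canonical pose sequence
#'
#' Applies [leg_lengths()] + [joint_angle()] to every angle definition at
#' every frame. A frame containing a degenerate triple (vertex coinciding
#' with an endpoint) is dropped with a warning, consistent with the
#' visibility-cleaning policy.
#'
#' @param seq a canonical [pose_sequence()].
#' @param angle_set angle definitions (default: [default_angle_set()] for the
#'   sequence's dialect).
#' @return object of class `joint_angle_series`: list with `angles`
#'   (`T x J` matrix, degrees, columns in the fixed angle order), `frames`,
#'   `subject_id`, `view`, `body_part`.
#' @export
extract_angle_series <- function(seq, angle_set = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!seq$dialect %in% c("canonical16", "coco18-canonical")) {
    stop_gm("extract_angle_series expects a canonical sequence; canonicalize() first")
  }
  if (is.null(angle_set)) angle_set <- default_angle_set(seq$dialect)
  jn <- joint_names(seq)
  missing <- setdiff(unique(c(angle_set$proximal, angle_set$vertex, angle_set$distal)), jn)
  if (length(missing)) {
    stop_gm("angle set requires joints absent from sequence: %s",
            paste(missing, collapse = ", "))
  }
  tt <- n_frames(seq)
  nj <- nrow(angle_set)
  ang <- matrix(NA_real_, tt, nj, dimnames = list(NULL, angle_set$name))
  degenerate <- rep(FALSE, tt)
  for (k in seq_len(nj)) {
    p <- joint_xy(seq, angle_set$proximal[k])
    v <- joint_xy(seq, angle_set$vertex[k])
    n <- joint_xy(seq, angle_set$distal[k])
    a <- sqrt(rowSums((v - p)^2))
    b <- sqrt(rowSums((v - n)^2))
    cc <- sqrt(rowSums((p - n)^2))
    bad <- a == 0 | b == 0
    degenerate <- degenerate | bad
    arg <- (a^2 + b^2 - cc^2) / (2 * a * b)
    arg <- pmin(1, pmax(-1, arg))
    ang[, k] <- acos(arg) * 180 / pi
    ang[bad, k] <- NA_real_
  }
  if (any(degenerate)) {
    warning(sprintf("%d frame(s) with degenerate joint triples dropped",
                    sum(degenerate)), call. = FALSE)
  }
  keep <- !degenerate
  joint_angle_series(ang[keep, , drop = FALSE], frames = seq$frames[keep],
                     subject_id = seq$subject_id, view = seq$view)
}

#' Construct a joint-angle series
#'
#' @param angles `T x J` numeric matrix of angles in degrees with angle-name
#'   column names.
#' @param frames optional frame indices.
#' @param subject_id,view labels.
#' @param body_part which body-part selection the columns represent.
#' @return object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(angles, frames = NULL, subject_id = NA,
                               view = NA, body_part = "whole") {
  angles <- as.matrix(angles)
  if (is.null(colnames(angles))) stop_gm("angle matrix must have column names")
  if (any(angles < -1e-9 | angles > 180 + 1e-9, na.rm = TRUE)) {
    stop_gm("angles must lie in [0, 180] degrees")
  }
  if (is.null(frames)) frames <- seq_len(nrow(angles)) - 1L
  structure(
    list(angles = angles, frames = as.integer(frames), subject_id = subject_id,
         view = view, body_part = body_part),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> subject=%s view=%s part=%s | T=%d frames x %d angles\n",
              as.character(x$subject_id), as.character(x$view), x$body_part,
              nrow(x$angles), ncol(x$angles)))
  cat("  angles:", paste(colnames(x$angles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.joint_angle_series <- function(x) dim(x$angles)

#' Select whole/upper/lower body-part angle columns
#'
#' `upper` keeps the left and right elbow angles; `lower` keeps everything
#' else (hips, knees and — when the skeleton has feet — ankles); `whole` is
#' the identity. Column order is preserved. Requesting columns that the angle
#' set cannot supply (e.g. ankles on COCO-18 data) returns the available
#' subset with a warning.
#'
#' @param series a [joint_angle_series()].
#' @param part `"whole"`, `"upper"` or `"lower"`.
#' @return a `joint_angle_series` with the selected columns.
#' @export
select_body_part <- function(series, part = c("whole", "upper", "lower")) {
  part <- match.arg(part)
  stopifnot(inherits(series, "joint_angle_series"))
  if (part == "whole") {
    series$body_part <- "whole"
    return(series)
  }
  cols <- colnames(series$angles)
  want <- if (part == "upper") UPPER_ANGLES else setdiff(ANGLE_ORDER_FULL, UPPER_ANGLES)
  have <- intersect(cols, want)   # preserves `cols` order
  if (length(have) < length(intersect(ANGLE_ORDER_FULL, want)) &&
      !setequal(cols, ANGLE_ORDER_COCO)) {
    warning(sprintf("body part '%s': only %d of its angles are present", part,
                    length(have)), call. = FALSE)
  }
  if (length(have) == 0) stop_gm("no '%s' body-part angles present", part)
  out <- series
  out$angles <- series$angles[, have, drop = FALSE]
  out$body_part <- part
  out
}

#' Write a joint-angle series as CSV
#'
#' One row per frame: a `frame` column followed by one column per angle.
#'
#' @param series a [joint_angle_series()].
#' @param path output file.
#' @export
write_angle_csv <- function(series, path) {
  stopifnot(inherits(series, "joint_angle_series"))
  df <- data.frame(frame = series$frames)
  for (nm in colnames(series$angles)) df[[nm]] <- fmt_num(series$angles[, nm])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a joint-angle series CSV written by [write_angle_csv()]
#'
#' @param path input file.
#' @param subject_id,view labels.
#' @return a [joint_angle_series()].
#' @export
read_angle_csv <- function(path, subject_id = NA, view = NA) {
  df <- read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(df)) stop_gm("angle CSV must have a 'frame' column")
  m <- as.matrix(df[, setdiff(names(df), "frame"), drop = FALSE])
  rownames(m) <- NULL
  joint_angle_series(m, frames = df$frame, subject_id = subject_id, view = view)
}
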