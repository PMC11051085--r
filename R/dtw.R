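# Dependent multi-dimensional DTW distance, warping path, feature distances.

#' Local cost between two feature vectors
#'
#' The ground metric of dependent multi-dimensional DTW: the Euclidean norm
#' of the difference across all feature dimensions. Reduces to `|x - y|` in
#' one dimension.
#'
#' @param u_vec,v_vec numeric vectors of equal length.
#' @return non-negative cost.
#' @export
local_cost <- function(u_vec, v_vec) {
  if (length(u_vec) != length(v_vec)) stop_gm("vectors must share dimensionality")
  sqrt(sum((u_vec - v_vec)^2))
}

as_feature_matrix <- function(x) {
  if (inherits(x, "joint_angle_series")) return(unname(x$angles))
  if (inherits(x, "correlation_feature")) return(unname(x$matrix))
  if (is.null(dim(x))) return(matrix(as.numeric(x), ncol = 1))
  unname(as.matrix(x))
}

#' Dynamic time warping distance between two feature matrices
#'
#' Classic dynamic-programming DTW with the symmetric three-way step pattern
#' (match / insert / delete, unit weights) and no window constraint. Rows are
#' sequence steps; columns are feature dimensions warped jointly (dependent
#' DTW: the local cost is the Euclidean norm across dimensions). The distance
#' is the raw accumulated cost along the optimal monotone, continuous warping
#' path from `(1, 1)` to `(T1, T2)`; backtracking prefers the diagonal step
#' on ties.
#'
#' @param A,B numeric matrices `T1 x J` and `T2 x J` (1-D numeric vectors are
#'   treated as single-column matrices).
#' @param keep_cost if `TRUE`, the accumulated-cost and local-cost matrices
#'   are kept in the result (for inspection and plotting).
#' @return object of class `dtw_result`: list with `distance`, `path`
#'   (`L x 2` matrix of 1-based index pairs), and optionally `cost`, `local`.
#' @export
dtw_distance <- function(A, B, keep_cost = FALSE) {
  A <- as_feature_matrix(A)
  B <- as_feature_matrix(B)
  if (nrow(A) < 1 || nrow(B) < 1) stop_gm("empty input sequence")
  if (ncol(A) != ncol(B)) stop_gm("inputs must share dimensionality J")
  res <- dtw_core(A, B, keep_cost)
  structure(
    list(distance = res$distance,
         path = res$path,
         cost = res$cost,
         local = res$local,
         n = c(nrow(A), nrow(B))),
    class = "dtw_result"
  )
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance = %.6g | %d x %d grid, path length %d\n",
              x$distance, x$n[1], x$n[2], nrow(x$path)))
  invisible(x)
}

#' Plot a DTW accumulated-cost matrix with its warping path
#'
#' Heat map of the accumulated-cost grid (reference index on the y axis,
#' probe index on the x axis) with the optimal warping path overlaid; a
#' near-diagonal path indicates well-matched sequences. Requires a result
#' computed with `keep_cost = TRUE`.
#'
#' @param x a [dtw_distance()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.dtw_result <- function(x, ...) {
  if (is.null(x$cost)) stop_gm("re-run dtw_distance() with keep_cost = TRUE to plot")
  graphics::image(seq_len(nrow(x$cost)), seq_len(ncol(x$cost)), x$cost,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "reference frame", ylab = "probe frame", ...)
  graphics::lines(x$path[, 1], x$path[, 2], lwd = 2)
  invisible(x)
}

#' Write a DTW result (cost matrix and path) to CSV/JSON
#'
#' Dumps the accumulated-cost grid as CSV and the warping path + distance as
#' JSON, for external visualization.
#'
#' @param result a [dtw_distance()] result with `keep_cost = TRUE`.
#' @param cost_path,path_path output files (either may be `NULL` to skip).
#' @export
write_dtw_result <- function(result, cost_path = NULL, path_path = NULL) {
  stopifnot(inherits(result, "dtw_result"))
  if (!is.null(cost_path)) {
    if (is.null(result$cost)) stop_gm("result has no cost matrix; use keep_cost = TRUE")
    utils::write.table(result$cost, cost_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(path_path)) {
    jsonlite::write_json(
      list(distance = result$distance,
           path = unname(apply(result$path, 1, as.list))),
      path_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(result)
}

#' DTW distance between two gait features of the same kind
#'
#' Angle features are `T x J` time series and are warped over the time axis.
#' A correlation feature is a `J x J` matrix stored as `J` ordered rows (one
#' per angle, in the fixed angle order); it is fed to DTW as a length-`J`
#' sequence of `J`-dimensional row vectors.
#'
#' @param ref_feature,tgt_feature two [joint_angle_series()] objects
#'   (`feature_kind = "angles"`) or two [correlation_matrix()] results
#'   (`feature_kind = "correlation"`).
#' @param feature_kind `"angles"` or `"correlation"`.
#' @return non-negative DTW distance.
#' @export
feature_distance <- function(ref_feature, tgt_feature,
                             feature_kind = c("angles", "correlation")) {
  feature_kind <- match.arg(feature_kind)
  want <- if (feature_kind == "angles") "joint_angle_series" else "correlation_feature"
  if (!inherits(ref_feature, want) || !inherits(tgt_feature, want)) {
    stop_gm("feature_kind '%s' expects two %s objects", feature_kind, want)
  }
  dtw_distance(as_feature_matrix(ref_feature), as_feature_matrix(tgt_feature))$distance
}
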