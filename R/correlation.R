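# Spearman rank-correlation features between joint-angle columns.

#' Fractional (tied-average) ranks
#'
#' Assigns ascending ranks 1..T; runs of equal values all receive the
#' arithmetic mean of the integer ranks they span, so the rank sum is always
#' exactly `T(T+1)/2`.
#'
#' @param values numeric vector of length `T >= 2`.
#' @return numeric rank vector.
#' @examples
#' rank_with_ties(c(5, 1, 3, 3, 9))  # 4.0 1.0 3.5 3.5 5.0
#' @export
rank_with_ties <- function(values) {
  tt <- length(values)
  if (tt < 2) stop_gm("need at least 2 values to rank")
  if (anyNA(values)) stop_gm("NA values cannot be ranked")
  ord <- order(values)
  sorted <- values[ord]
  ranks_sorted <- numeric(tt)
  i <- 1L
  while (i <= tt) {
    j <- i
    while (j < tt && sorted[j + 1L] == sorted[i]) j <- j + 1L
    ranks_sorted[i:j] <- mean(i:j)
    i <- j + 1L
  }
  out <- numeric(tt)
  out[ord] <- ranks_sorted
  out
}

#' Spearman rank correlation of two sequences
#'
#' Pearson product-moment correlation of the two tied-average rank vectors,
#' computed as
#' `(E[XY] - E[X]E[Y]) / sqrt((E[X^2]-E[X]^2)(E[Y^2]-E[Y]^2))`
#' with expectations as arithmetic means over the `T` frames. A constant
#' input has zero rank variance; its correlation is defined as 0 ("no
#' monotone relationship") with a warning rather than a division by zero.
#'
#' @param x,y numeric vectors of equal length `T >= 2`.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_pair <- function(x, y) {
  if (length(x) != length(y)) stop_gm("x and y must have equal length")
  rx <- rank_with_ties(x)
  ry <- rank_with_ties(y)
  vx <- mean(rx^2) - mean(rx)^2
  vy <- mean(ry^2) - mean(ry)^2
  if (vx == 0 || vy == 0) {
    warning("zero-variance input; Spearman correlation set to 0", call. = FALSE)
    return(0)
  }
  r <- (mean(rx * ry) - mean(rx) * mean(ry)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Spearman correlation matrix of a joint-angle series
#'
#' The frame-count-independent gait signature: entry `(u, v)` is
#' [spearman_pair()] of angle columns `u` and `v` over the whole sequence.
#' Computed on the upper triangle and mirrored, so the matrix is symmetric by
#' construction with a unit diagonal for non-degenerate columns.
#'
#' @param series a [joint_angle_series()] with `T >= 2` frames and `J >= 2`
#'   angle columns.
#' @return object of class `correlation_feature`: list with `matrix`
#'   (`J x J`), `angle_names`, `subject_id`, `view`.
#' @export
correlation_matrix <- function(series) {
  stopifnot(inherits(series, "joint_angle_series"))
  m <- series$angles
  if (nrow(m) < 2) stop_gm("need at least 2 frames for a correlation")
  nj <- ncol(m)
  if (nj < 2) stop_gm("need at least 2 angle columns for a correlation matrix")
  ranks <- apply(m, 2L, rank_with_ties)
  vars <- colMeans(ranks^2) - colMeans(ranks)^2
  if (any(vars == 0)) {
    warning(sprintf("constant angle column(s): %s; correlations set to 0",
                    paste(colnames(m)[vars == 0], collapse = ", ")), call. = FALSE)
  }
  cm <- diag(nj)
  for (u in seq_len(nj - 1L)) {
    for (v in (u + 1L):nj) {
      r <- if (vars[u] == 0 || vars[v] == 0) 0 else {
        val <- (mean(ranks[, u] * ranks[, v]) - mean(ranks[, u]) * mean(ranks[, v])) /
          sqrt(vars[u] * vars[v])
        min(1, max(-1, val))
      }
      cm[u, v] <- r
      cm[v, u] <- r
    }
  }
  dimnames(cm) <- list(colnames(m), colnames(m))
  structure(
    list(matrix = cm, angle_names = colnames(m),
         subject_id = series$subject_id, view = series$view),
    class = "correlation_feature"
  )
}

#' @export
print.correlation_feature <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_feature> subject=%s view=%s | %d x %d Spearman matrix\n",
              as.character(x$subject_id), as.character(x$view),
              nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Write a correlation feature to JSON or square CSV
#'
#' JSON: `{subject, view, angle_names, matrix}`. CSV: square matrix with the
#' angle names as header row and first column.
#'
#' @param feature a [correlation_matrix()] result.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_correlation <- function(feature, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(feature, "correlation_feature"))
  if (format == "json") {
    jsonlite::write_json(
      list(subject = feature$subject_id, view = feature$view,
           angle_names = feature$angle_names,
           matrix = unname(feature$matrix)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    df <- data.frame(angle = feature$angle_names, feature$matrix,
                     check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
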