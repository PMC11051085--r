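# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps all package randomness seedable
# without clobbering the user's global RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and small component indices; stays
# well below .Machine$integer.max for the index ranges used here.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in seq_along(idx)) s <- (s * 31 + idx[k] * (k + 6)) %% 2147480000
  as.integer(s) + 1L
}

# Full-precision numeric formatting so CSV round-trips are bit-exact.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

stop_gm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
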