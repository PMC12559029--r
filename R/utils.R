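# Shared internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# (config, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Root mean square of a signal
#'
#' Plain quadratic mean over the full segment, `sqrt(mean(x^2))`, with no
#' detrending; generated signals are explicitly mean-centered upstream so the
#' RMS and the standard deviation coincide for them.
#'
#' @param x Numeric vector.
#' @return Nonnegative scalar.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Validate a segment or matrix of segments: finite numeric, positive length.
check_segments <- function(x, name = "x") {
  if (!is.numeric(x) || length(x) == 0L) {
    stop(sprintf("`%s` must be a nonempty numeric vector or matrix", name),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce a vector or (segments x samples) matrix to a matrix with one
# segment per row.
as_segment_matrix <- function(x, name = "x") {
  check_segments(x, name)
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_same_shape <- function(a, b, na = "x_hat", nb = "x") {
  if (length(a) != length(b)) {
    stop(sprintf("`%s` and `%s` must have the same length (%d vs %d)",
                 na, nb, length(a), length(b)), call. = FALSE)
  }
  invisible(NULL)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
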