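# Classical penalized low-rank + sparse decomposition: the iterative solver
# the network unfolds.  A 1-D segment acquires matrix rank through a window
# embedding (consecutive time windows as columns, or a Hankel matrix); the
# solver then alternates singular value thresholding on the low-rank part and
# soft thresholding on the sparse part of
#     min_{D,N}  ||D||_* + mu ||N||_1 + beta/2 ||R - D - N||_F^2 .

#' Window-embedding specification
#'
#' `"reshape"` stacks consecutive length-`rows` windows as columns
#' (`rows * cols == segment length`); `"hankel"` builds the Hankel matrix
#' `M[i, j] = s[i + j - 1]` (`rows + cols - 1 == segment length`).
#'
#' @param rows,cols Matrix dimensions.
#' @param mode `"reshape"` or `"hankel"`.
#' @return A list of class `"window_embedding"`.
#' @export
window_embedding <- function(rows = 16L, cols = 32L,
                             mode = c("reshape", "hankel")) {
  mode <- match.arg(mode)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 mode = mode),
            class = "window_embedding")
}

embedding_length <- function(spec) {
  if (spec$mode == "reshape") spec$rows * spec$cols
  else spec$rows + spec$cols - 1L
}

#' Embed a 1-D segment as a matrix
#'
#' @param s Numeric segment.
#' @param spec A [window_embedding()] consistent with `length(s)`.
#' @return A `rows x cols` matrix.
#' @export
embed_segment <- function(s, spec = window_embedding()) {
  check_segments(s, "s")
  if (length(s) != embedding_length(spec)) {
    stop(sprintf("embedding (%d x %d, %s) inconsistent with length %d",
                 spec$rows, spec$cols, spec$mode, length(s)), call. = FALSE)
  }
  if (spec$mode == "reshape") {
    matrix(s, nrow = spec$rows)
  } else {
    outer(seq_len(spec$rows), seq_len(spec$cols),
          function(i, j) s[i + j - 1L])
  }
}

#' Invert a window embedding
#'
#' Exact for `"reshape"`; anti-diagonal averaging for `"hankel"` (exact on
#' matrices that are themselves Hankel).
#'
#' @param M Matrix.
#' @param spec The [window_embedding()] used to build it.
#' @return Numeric segment.
#' @export
unembed_segment <- function(M, spec = window_embedding()) {
  stopifnot(is.matrix(M))
  if (nrow(M) != spec$rows || ncol(M) != spec$cols) {
    stop("matrix shape inconsistent with the embedding spec", call. = FALSE)
  }
  if (spec$mode == "reshape") {
    as.numeric(M)
  } else {
    idx <- outer(seq_len(spec$rows), seq_len(spec$cols), `+`) - 1L
    as.numeric(tapply(M, idx, mean))
  }
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm:
#' `U diag(max(sigma - alpha, 0)) V'`.
#'
#' @param M Numeric matrix.
#' @param alpha Nonnegative threshold.
#' @return Matrix of the same shape with shrunken singular values.
#' @export
svt <- function(M, alpha) {
  stopifnot(is.matrix(M))
  check_segments(M, "M")
  check_scalar(alpha, "alpha", nonnegative = TRUE)
  if (alpha == 0) return(M)
  sv <- svd(M)
  d <- pmax(sv$d - alpha, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Soft thresholding
#'
#' The proximal operator of the l1 norm: `sign(v) * max(|v| - tau, 0)`.
#'
#' @param v Numeric vector, matrix or array.
#' @param tau Nonnegative threshold.
#' @return Object of the same shape.
#' @export
soft_threshold <- function(v, tau) {
  check_segments(v, "v")
  check_scalar(tau, "tau", nonnegative = TRUE)
  sign(v) * pmax(abs(v) - tau, 0)
}

lrr_objective <- function(R, D, N, mu, beta) {
  sum(svd(D, nu = 0, nv = 0)$d) + mu * sum(abs(N)) +
    beta / 2 * sum((R - D - N)^2)
}

#' Penalized low-rank + sparse decomposition
#'
#' Alternates `D <- svt(R - N, 1/beta)` and
#' `N <- soft_threshold(R - D, mu/beta)` — each step exactly minimizes the
#' penalized objective in one block, so the objective is monotonically
#' nonincreasing — until the relative Frobenius change of `(D, N)` drops
#' below `tol` or `max_iter` is reached.
#'
#' @param R Observed matrix.
#' @param mu Positive balance weight on the sparse part. The default suits
#'   unit-scale entries; for recovery-grade accuracy tune `(mu, beta)` to the
#'   noise magnitude.
#' @param beta Positive quadratic penalty coefficient.
#' @param max_iter Iteration cap.
#' @param tol Relative-change stopping threshold.
#' @return An object of class `"lrr_decomp"`: fields `D`, `N`,
#'   `objective_history`, `iterations_run`, `converged`.
#' @export
lrr_decompose <- function(R, mu = 0.15, beta = 5, max_iter = 500L,
                          tol = 1e-7) {
  stopifnot(is.matrix(R))
  check_segments(R, "R")
  check_scalar(mu, "mu", positive = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  check_scalar(tol, "tol", positive = TRUE)
  D <- matrix(0, nrow(R), ncol(R))
  N <- matrix(0, nrow(R), ncol(R))
  history <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    D_new <- svt(R - N, 1 / beta)
    N_new <- soft_threshold(R - D_new, mu / beta)
    history[it] <- lrr_objective(R, D_new, N_new, mu, beta)
    delta <- sqrt(sum((D_new - D)^2) + sum((N_new - N)^2)) /
      max(1, sqrt(sum(D_new^2) + sum(N_new^2)))
    D <- D_new
    N <- N_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(D = D, N = N, objective_history = history[seq_len(it)],
                 iterations_run = it, converged = converged,
                 mu = mu, beta = beta),
            class = "lrr_decomp")
}

#' @export
print.lrr_decomp <- function(x, ...) {
  cat(sprintf("Low-rank + sparse decomposition (%d x %d)\n",
              nrow(x$D), ncol(x$D)))
  cat(sprintf("  mu = %g, beta = %g\n", x$mu, x$beta))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations_run,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective: %.6g\n",
              x$objective_history[length(x$objective_history)]))
  cat(sprintf("  rank(D) (numerical): %d, nnz(N): %d / %d\n",
              sum(svd(x$D, nu = 0, nv = 0)$d > 1e-8 * max(1e-12, svd(x$D, nu = 0, nv = 0)$d[1])),
              sum(x$N != 0), length(x$N)))
  invisible(x)
}

#' Majorized noise update of the iterative solver
#'
#' The closed-form minimizer of the quadratic (Taylor/Lipschitz) surrogate of
#' the noise regularizer:
#' `delta * N_prev + (1 - delta) * (R_prev - D_cur) - rho * grad_s(N_prev)`
#' with `delta = mu*ls / (mu*ls + beta)` and `rho = mu / (mu*ls + beta)`.
#' This is the update the network's noise stage learns, with `delta` frozen
#' and `rho` made learnable.
#'
#' @param n_prev Previous noise estimate (array).
#' @param r_prev Previous raw-signal estimate, same shape.
#' @param d_cur Current clean estimate, same shape.
#' @param mu,beta Positive solver weights.
#' @param ls Positive Lipschitz constant of the regularizer gradient.
#' @param grad_s Function mapping an array to the regularizer gradient, same
#'   shape.
#' @return Updated noise array.
#' @export
surrogate_update_n <- function(n_prev, r_prev, d_cur, mu, beta, ls,
                               grad_s = function(n) 0 * n) {
  check_scalar(mu, "mu", positive = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  check_scalar(ls, "ls", positive = TRUE)
  if (length(n_prev) != length(r_prev) || length(n_prev) != length(d_cur)) {
    stop("`n_prev`, `r_prev`, `d_cur` must share one shape", call. = FALSE)
  }
  g <- grad_s(n_prev)
  if (length(g) != length(n_prev)) {
    stop("`grad_s` must preserve shape", call. = FALSE)
  }
  delta <- mu * ls / (mu * ls + beta)
  rho <- mu / (mu * ls + beta)
  delta * n_prev + (1 - delta) * (r_prev - d_cur) - rho * g
}

#' Classical denoising of a 1-D segment
#'
#' Embeds the segment, runs [lrr_decompose()], and un-embeds the low-rank
#' (clean) and sparse (noise) parts. In `"reshape"` mode the two outputs sum
#' to the input exactly up to the solver residual split.
#'
#' @param y Noisy segment.
#' @param spec A [window_embedding()] consistent with `length(y)`.
#' @param mu,beta,max_iter,tol Passed to [lrr_decompose()].
#' @return List with `x_hat`, `n_hat` and the `"lrr_decomp"` object.
#' @export
classical_denoise <- function(y, spec = window_embedding(),
                              mu = 0.15, beta = 5, max_iter = 500L,
                              tol = 1e-7) {
  M <- embed_segment(y, spec)
  dec <- lrr_decompose(M, mu = mu, beta = beta, max_iter = max_iter,
                       tol = tol)
  resid <- M - dec$D - dec$N
  # attribute the quadratic-penalty residual to the clean part so the
  # additive split x_hat + n_hat = y holds exactly in reshape mode
  x_hat <- unembed_segment(dec$D + resid, spec)
  n_hat <- unembed_segment(dec$N, spec)
  list(x_hat = x_hat, n_hat = n_hat, decomposition = dec)
}
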