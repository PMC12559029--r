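test_that("window embeddings round-trip and expose low rank", {
  s <- rnorm(512)
  spec <- window_embedding(16, 32, "reshape")
  expect_identical(unembed_segment(embed_segment(s, spec), spec), s)

  hspec <- window_embedding(20, 13, "hankel")
  sc <- rep(3.5, 32)
  H <- embed_segment(sc, hspec)
  expect_true(all(H == 3.5))
  expect_equal(qr(H)$rank, 1L)
  sh <- rnorm(32)
  expect_equal(unembed_segment(embed_segment(sh, hspec), hspec), sh,
               tolerance = 1e-12)

  # any equally spaced windowing of a sinusoid spans at most two directions
  t <- (0:511) / 256
  M <- embed_segment(sin(2 * pi * 8 * t), spec)
  sv <- svd(M)$d
  expect_lt(sv[3], 1e-8 * sv[1])

  expect_error(embed_segment(s, window_embedding(10, 10, "reshape")),
               "inconsistent")
})

test_that("singular value thresholding matches its proximal objective", {
  M <- diag(c(5, 1))
  expect_equal(svt(M, 2), diag(c(3, 0)))
  R <- matrix(rnorm(12), 3)
  expect_identical(svt(R, 0), R)

  # nuclear norm of the output equals the shrunken singular values
  sv <- svd(R)$d
  expect_equal(sum(svd(svt(R, 0.4))$d), sum(pmax(sv - 0.4, 0)),
               tolerance = 1e-12)

  # proximal oracle: brute-force minimization of a ||X||_* + 0.5 ||X - M||_F^2.
  # Instances draw random orthogonal factors with singular values bounded
  # away from the threshold, where the objective is smooth at the optimum and
  # a quasi-Newton minimizer is a trustworthy independent reference.
  set.seed(20)
  for (rep in seq_len(20)) {
    q1 <- qr.Q(qr(matrix(rnorm(16), 4)))
    q2 <- qr.Q(qr(matrix(rnorm(16), 4)))
    M4 <- q1 %*% diag(runif(4, 1.2, 4)) %*% t(q2)
    alpha <- 0.7
    obj <- function(v) {
      X <- matrix(v, 4)
      alpha * sum(svd(X, nu = 0, nv = 0)$d) + 0.5 * sum((X - M4)^2)
    }
    opt <- optim(as.numeric(M4), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_equal(as.numeric(svt(M4, alpha)), opt$par, tolerance = 1e-5)
  }
})

test_that("soft thresholding matches its elementwise proximal objective", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  v <- rnorm(20)
  expect_identical(soft_threshold(v, 0), v)
  expect_error(soft_threshold(v, -0.1), ">= 0")

  set.seed(21)
  for (rep in seq_len(20)) {
    v10 <- rnorm(10)
    tau <- 0.3
    oracle <- vapply(v10, function(vi) {
      optimize(function(u) tau * abs(u) + 0.5 * (u - vi)^2,
               c(-10, 10), tol = 1e-10)$minimum
    }, numeric(1))
    expect_equal(soft_threshold(v10, tau), oracle, tolerance = 1e-6)
  }
})

test_that("the majorized noise update matches its closed form and objective", {
  set.seed(22)
  n_prev <- rnorm(8); r_prev <- rnorm(8); d_cur <- rnorm(8)

  # mu*ls == beta makes delta = 1/2
  out <- surrogate_update_n(n_prev, r_prev, d_cur, mu = 2, beta = 2, ls = 1)
  expect_equal(out, 0.5 * n_prev + 0.5 * (r_prev - d_cur))

  # fixed point when the residual split is already consistent
  fp <- surrogate_update_n(r_prev - d_cur, r_prev, d_cur,
                           mu = 1.3, beta = 0.7, ls = 2.1)
  expect_equal(fp, r_prev - d_cur)

  # quadratic regularizer S(N) = 0.5 ||N||^2: the update must equal the
  # numerical argmin of mu * S_hat(N | N_prev) + beta/2 ||R - D - N||^2
  for (rep in seq_len(20)) {
    mu <- runif(1, 0.1, 3); beta <- runif(1, 0.1, 3); ls <- 1
    np <- rnorm(8); rp <- rnorm(8); dc <- rnorm(8)
    obj <- function(N) {
      anchor <- np - (1 / ls) * np       # N_prev - grad S(N_prev) / ls
      mu * (ls / 2) * sum((N - anchor)^2) + beta / 2 * sum((rp - dc - N)^2)
    }
    opt <- optim(np, obj, method = "BFGS", control = list(reltol = 1e-14))
    closed <- surrogate_update_n(np, rp, dc, mu, beta, ls,
                                 grad_s = function(n) n)
    expect_equal(closed, opt$par, tolerance = 1e-6)
    # the three coefficients sum to one: delta + beta/(mu*ls+beta) == 1
    delta <- mu * ls / (mu * ls + beta)
    expect_equal(delta + beta / (mu * ls + beta), 1, tolerance = 1e-12)
  }
  expect_error(surrogate_update_n(rnorm(4), rnorm(8), rnorm(8), 1, 1, 1),
               "shape")
})

test_that("the alternating solver recovers structured decompositions", {
  # no-noise limit: a rank-1 observation with a large sparsity weight
  u <- rnorm(16); v <- rnorm(16)
  R1 <- u %o% v
  dec1 <- lrr_decompose(R1, mu = 50, beta = 50, max_iter = 200)
  expect_lt(max(abs(dec1$N)), 1e-8)
  expect_equal(dec1$D, R1, tolerance = 1e-2)

  dec0 <- lrr_decompose(matrix(0, 8, 8), mu = 1, beta = 1)
  expect_true(all(dec0$D == 0) && all(dec0$N == 0))

  inst <- rank2_sparse_instance()
  dec <- lrr_decompose(inst$R, mu = 0.15, beta = 10, max_iter = 500,
                       tol = 1e-9)
  expect_lte(dec$iterations_run, 500L)
  expect_lt(sqrt(sum((dec$D - inst$L)^2)) / sqrt(sum(inst$L^2)), 1e-2)
  expect_true(all(diff(dec$objective_history) <= 1e-10))
})

test_that("classical denoising splits tones from spikes additively", {
  t <- (0:511) / 256
  clean <- sin(2 * pi * 8 * t)
  spec <- window_embedding(16, 32, "reshape")
  cd <- classical_denoise(clean, spec, mu = 5, beta = 5)
  expect_lt(rrmse_temporal(cd$x_hat, clean), 0.05)
  expect_equal(cd$x_hat + cd$n_hat, clean, tolerance = 1e-10)

  set.seed(23)
  spk <- sample(512, 3)
  amp <- c(6, -7, 8)
  noisy <- clean
  noisy[spk] <- noisy[spk] + amp
  cd2 <- classical_denoise(noisy, spec, mu = 0.2, beta = 5)
  expect_equal(cd2$x_hat + cd2$n_hat, noisy, tolerance = 1e-10)
  expect_gte(sum(cd2$n_hat[spk]^2) / sum(amp^2), 0.8)

  expect_error(classical_denoise(rnorm(100), spec), "inconsistent")
})
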