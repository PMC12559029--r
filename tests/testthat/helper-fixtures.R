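# Shared fixtures: tiny network configurations for fast structural tests and
# the reference synthetic experiment ("budget") used by the end-to-end and
# ablation checks.

# A deliberately small unfolded model for structural/gradient tests.
tiny_config <- function(K = 1L, ...) {
  unfold_config(K = K,
                netd = netd_config(depth = 2L, channels = c(2L, 3L)),
                netn = netn_config(n_layers = 2L, channels = 2L),
                netr = netr_config(n_layers = 2L, channels = 2L),
                ...)
}

# The reference synthetic experiment: 200/20/20 clean split, 2000 training
# mixtures (200 x 10 shuffles), deterministic 10-SNR evaluation grids.
budget_bundle <- function(kind) {
  synthetic_bundle(n_clean = 240L, n_artifact = 200L, artifact_kind = kind,
                   ratios = c(10, 1, 1), seed = 100L)
}

budget_config <- function(K = 3L, ...) {
  unfold_config(K = K,
                netd = netd_config(depth = 3L, channels = c(4L, 8L, 16L)),
                netn = netn_config(n_layers = 3L, channels = 8L),
                netr = netr_config(n_layers = 2L, channels = 8L),
                ...)
}

budget_control <- function(seed = 0L) {
  train_control(lr = 1e-4, batch_size = 32L, max_epochs = 6L, patience = 5L,
                seed = seed)
}

mean_snr <- function(x_hat, x) {
  mean(vapply(seq_len(nrow(x)), function(i) snr_db_pair(x_hat[i, ], x[i, ]),
              numeric(1)))
}

# Jitter every parameter of a model: gradient-flow checks must be run at a
# generic parameter point, not at the identity initialization where the
# zero final projections block upstream gradient paths by construction.
jitter_params <- function(model, sd = 0.05, seed = 1L) {
  model$params <- lrrunet:::with_seed(seed, lapply(model$params, function(p) {
    p + stats::rnorm(length(p), sd = sd)
  }))
  model
}

# Ground-truth low-rank + sparse instance of the recovery experiment.
rank2_sparse_instance <- function(n = 32L, frac = 0.05, magnitude = 5,
                                  seed = 11L) {
  lrrunet:::with_seed(seed, {
    L <- rnorm(n) %o% rnorm(n) + rnorm(n) %o% rnorm(n)
    S <- matrix(0, n, n)
    idx <- sample(n * n, round(frac * n * n))
    S[idx] <- magnitude * sample(c(-1, 1), length(idx), replace = TRUE)
    list(L = L, S = S, R = L + S)
  })
}
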