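# Training-set construction and the optimization loop.  Training tests use
# short segments (length 32) and a tiny model so the loop itself is what is
# being exercised, not the architecture.

small_bundle <- function(n_clean = 30L, seed = 50L) {
  cfg <- synth_config(length = 32L)
  clean <- gen_clean(cfg, n_clean, seed = seed)
  artifact <- gen_emg(cfg, 25L, seed = seed + 1L)
  dataset_bundle(clean, artifact, "emg", ratios = c(0.6, 0.2, 0.2),
                 seed = seed + 2L)
}

test_that("splits are identity-disjoint and exhaustive", {
  b <- small_bundle()
  idx <- c(b$train_idx, b$val_idx, b$test_idx)
  expect_equal(sort(idx), seq_len(30L))
  expect_length(intersect(b$train_idx, b$val_idx), 0)
  expect_length(intersect(b$train_idx, b$test_idx), 0)
  expect_length(intersect(b$val_idx, b$test_idx), 0)
})

test_that("the training set realizes the shuffled n-repeats protocol", {
  b <- small_bundle()
  tr <- build_training_set(b, n_repeats = 10, seed = 51)
  expect_equal(nrow(tr$y), 10L * length(b$train_idx))
  expect_true(all(tr$snr >= -7 & tr$snr <= 2))
  expect_true(all(tr$clean_index %in% b$train_idx))
  # each repeat block is a permutation of the training identities
  blocks <- matrix(tr$clean_index, ncol = 10)
  for (j in 1:10) expect_setequal(blocks[, j], b$train_idx)
  # mixtures follow y = x + lam * n exactly
  expect_equal(tr$y, tr$x + tr$lam * tr$n, tolerance = 1e-12)

  tr2 <- build_training_set(b, n_repeats = 10, seed = 51)
  expect_identical(tr$lam, tr2$lam)
  expect_identical(tr$y, tr2$y)
  expect_error(build_training_set(b, n_repeats = 10, seed = 1,
                                  snr_range = c(-7, 2),
                                  convention = "nope"))
})

test_that("the evaluation grid covers every integer SNR deterministically", {
  b <- small_bundle()
  ev <- build_eval_set(b, "test")
  expect_equal(nrow(ev$y), 10L * length(b$test_idx))
  expect_setequal(unique(ev$snr), -7:2)
  expect_true(all(table(ev$snr) == length(b$test_idx)))
  # grouped by SNR level
  expect_equal(ev$snr, rep(-7:2, each = length(b$test_idx)))
  expect_identical(ev, build_eval_set(b, "test"))
  # measured SNR of each pair equals its level
  for (i in seq_len(nrow(ev$y))) {
    expect_equal(snr_db(mean(ev$x[i, ]^2), mean((ev$y[i, ] - ev$x[i, ])^2)),
                 ev$snr[i], tolerance = 1e-6)
  }
})

test_that("training reduces the loss and is reproducible", {
  b <- small_bundle(n_clean = 40L)
  tr <- build_training_set(b, n_repeats = 5, seed = 52)   # 120 mixtures
  va <- build_eval_set(b, "val")
  cfg <- tiny_config(K = 1)
  ctl <- train_control(lr = 1e-3, batch_size = 16, max_epochs = 4,
                       patience = 4, seed = 0)
  fit <- lrr_unet(tr, val = va, config = cfg, control = ctl)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(fit$best_epoch, which.min(h$val_loss))

  fit2 <- lrr_unet(tr, val = va, config = cfg, control = ctl)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("early stopping halts after `patience` flat epochs and keeps the best", {
  # stubbed validation schedule: improvement only up to epoch 2
  es <- list(best_loss = NULL, best_epoch = 0L, stop = FALSE)
  losses <- c(1.0, 0.5, 0.6, 0.7, 0.8)
  run <- 0L
  for (e in seq_along(losses)) {
    es <- lrrunet:::es_update(es, losses[e], e, patience = 1L)
    run <- e
    if (es$stop) break
  }
  expect_true(es$stop)
  expect_equal(es$best_epoch, 2L)
  expect_lte(run, es$best_epoch + 1L)

  # integration: epochs_run <= best_epoch + patience on a real fit
  b <- small_bundle(n_clean = 40L)
  tr <- build_training_set(b, n_repeats = 2, seed = 53)
  va <- build_eval_set(b, "val")
  ctl <- train_control(lr = 1e-3, batch_size = 16, max_epochs = 15,
                       patience = 2, seed = 1)
  fit <- lrr_unet(tr, val = va, config = tiny_config(K = 1), control = ctl)
  expect_lte(nrow(fit$history), fit$best_epoch + 2L)
  if (fit$stopped_early) {
    expect_lt(nrow(fit$history), 15L)
  }
})

test_that("the loss is tied to the configured output mode", {
  b <- small_bundle(n_clean = 40L)
  tr <- build_training_set(b, n_repeats = 2, seed = 54)
  ctl <- train_control(lr = 1e-3, batch_size = 16, max_epochs = 2,
                       patience = 2, seed = 2)
  fit_d <- lrr_unet(tr, config = tiny_config(K = 1, output_mode = "D_last"),
                    control = ctl)
  fit_r <- lrr_unet(tr, config = tiny_config(K = 1, output_mode = "R_last"),
                    control = ctl)
  expect_false(isTRUE(all.equal(fit_d$history$train_loss,
                                fit_r$history$train_loss)))
})

test_that("fit methods expose coefficients, predictions and residuals", {
  b <- small_bundle(n_clean = 40L)
  tr <- build_training_set(b, n_repeats = 2, seed = 55)
  va <- build_eval_set(b, "val")
  ctl <- train_control(lr = 1e-3, batch_size = 16, max_epochs = 2,
                       patience = 2, seed = 3)
  fit <- lrr_unet(tr, val = va, config = tiny_config(K = 2), control = ctl)

  expect_named(coef(fit), c("rho1", "rho2"))
  pred <- predict(fit, va$y)
  expect_equal(dim(pred), dim(va$y))
  res <- residuals(fit)
  expect_equal(res, va$y - pred, tolerance = 1e-12)
  expect_output(print(fit), "unfolded")
  expect_output(print(summary(fit)), "best epoch")

  tmp <- tempfile(fileext = ".rds")
  save_lrr_unet(fit, tmp)
  fit2 <- load_lrr_unet(tmp)
  expect_identical(fit2$model$params, fit$model$params)
  expect_equal(predict(fit2, va$y), pred)
  unlink(tmp)
})
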