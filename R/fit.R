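# Model fitting: MSE loss, Adam, early stopping on validation loss.

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience: epochs without validation
#'   improvement before training halts (the best epoch's parameters are
#'   restored either way).
#' @param seed Seed controlling initialization and batch shuffling.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param verbose Print one line per epoch.
#' @return A list of class `"train_control"`.
#' @export
train_control <- function(lr = 1e-4, batch_size = 64L, max_epochs = 200L,
                          patience = 10L, seed = 0L, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, verbose = FALSE) {
  check_scalar(lr, "lr", positive = TRUE)
  stopifnot(batch_size >= 1L, max_epochs >= 1L, patience >= 1L)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# One Adam update over the flat parameter list; `state` carries m, v, t.
adam_step <- function(params, grads, state, control) {
  state$t <- state$t + 1L
  bc1 <- 1 - control$beta1^state$t
  bc2 <- 1 - control$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- control$beta1 * state$m[[nm]] + (1 - control$beta1) * g
    state$v[[nm]] <- control$beta2 * state$v[[nm]] + (1 - control$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      control$lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + control$eps)
  }
  params
}

# Early-stopping bookkeeping: returns the updated state after observing the
# validation loss of `epoch`.
es_update <- function(state, loss, epoch, patience) {
  if (is.null(state$best_loss) || loss < state$best_loss) {
    state$best_loss <- loss
    state$best_epoch <- epoch
  }
  state$stop <- (epoch - state$best_epoch) >= patience
  state
}

# Standardize every (y, x) pair of a mixed set by sd(y).
standardize_set <- function(set) {
  scales <- apply(set$y, 1L, stats::sd)
  if (any(scales == 0)) stop("constant noisy segment in data", call. = FALSE)
  list(y = set$y / scales, x = set$x / scales, scales = scales)
}

as_xy <- function(data, name = "data") {
  if (inherits(data, "mixed_set")) return(data)
  if (is.list(data) && !is.null(data$y) && !is.null(data$x)) {
    return(list(y = as_segment_matrix(data$y), x = as_segment_matrix(data$x)))
  }
  stop(sprintf("`%s` must be a mixed_set or a list with `y` and `x`", name),
       call. = FALSE)
}

batched_loss <- function(model, ys, xs, benv, chunk = 128L) {
  n <- nrow(ys)
  total <- 0
  for (st in seq(1L, n, by = chunk)) {
    en <- min(n, st + chunk - 1L)
    yb <- array(t(ys[st:en, , drop = FALSE]), c(1L, ncol(ys), en - st + 1L))
    fw <- unfold_forward_ad(model, yb, training = FALSE, benv = benv)
    out <- ad_value(fw$output)
    xb <- array(t(xs[st:en, , drop = FALSE]), c(1L, ncol(xs), en - st + 1L))
    total <- total + sum((out - xb)^2)
  }
  total / length(ys)
}

#' Fit an LRR-Unet denoiser
#'
#' Trains the K-stage unfolded network by minimizing the mean squared error
#' between the configured model output (`D_last` by default) and the clean
#' target, both in per-pair standardized space (each noisy/clean pair divided
#' by the noisy segment's standard deviation). Adam optimization with early
#' stopping on the validation loss; the parameters of the best validation
#' epoch are restored.
#'
#' @param data Training data: a `"mixed_set"` from [build_training_set()] or
#'   a list with matrices `y` (noisy) and `x` (clean).
#' @param val Validation data in the same form, or `NULL` to disable early
#'   stopping.
#' @param config An [unfold_config()].
#' @param control A [train_control()].
#' @return An object of class `"lrr_unet"` with the fitted model, training
#'   history, and the validation set used.
#' @export
#' @examples
#' bundle <- synthetic_bundle(n_clean = 40, n_artifact = 30, seed = 1)
#' train <- build_training_set(bundle, n_repeats = 1, seed = 1)
#' cfg <- unfold_config(K = 1,
#'   netd = netd_config(depth = 2, channels = c(2, 4)),
#'   netn = netn_config(n_layers = 1, channels = 2),
#'   netr = netr_config(n_layers = 1, channels = 2))
#' fit <- lrr_unet(train, config = cfg,
#'                 control = train_control(max_epochs = 1, batch_size = 16))
#' print(fit)
lrr_unet <- function(data, val = NULL, config = unfold_config(),
                     control = train_control()) {
  data <- as_xy(data, "data")
  tr <- standardize_set(data)
  va <- if (!is.null(val)) standardize_set(as_xy(val, "val")) else NULL
  L <- ncol(tr$y)
  n <- nrow(tr$y)

  model <- build_lrr_unet(config, length = L, seed = control$seed)
  benv <- buffers_as_env(model$buffers)
  adam <- new.env(parent = emptyenv())
  adam$m <- lapply(model$params, function(p) p * 0)
  adam$v <- lapply(model$params, function(p) p * 0)
  adam$t <- 0L

  es <- list(best_loss = NULL, best_epoch = 0L, stop = FALSE)
  best <- list(params = model$params, buffers = buffers_from_env(benv))
  train_hist <- numeric(0)
  val_hist <- numeric(0)
  stopped_early <- FALSE

  with_seed(control$seed, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (bi in seq(1L, n, by = control$batch_size)) {
        idx <- ord[bi:min(n, bi + control$batch_size - 1L)]
        yb <- array(t(tr$y[idx, , drop = FALSE]), c(1L, L, length(idx)))
        xb <- array(t(tr$x[idx, , drop = FALSE]), c(1L, L, length(idx)))
        fw <- unfold_forward_ad(model, yb, training = TRUE, benv = benv)
        loss <- ad_mse(fw$output, xb)
        lv <- ad_value(loss)
        if (!is.finite(lv)) {
          stop(sprintf("non-finite training loss in epoch %d, batch %d",
                       epoch, (bi - 1L) %/% control$batch_size + 1L),
               call. = FALSE)
        }
        ids <- vapply(fw$param_nodes, function(nd) nd$id, integer(1))
        grads <- ad_backward(loss, ids)
        model$params <- adam_step(model$params, grads, adam, control)
        batch_losses <- c(batch_losses, lv)
      }
      train_loss <- mean(batch_losses)
      val_loss <- if (!is.null(va)) {
        batched_loss(model, va$y, va$x, benv)
      } else NA_real_
      train_hist[epoch] <- train_loss
      val_hist[epoch] <- val_loss
      if (control$verbose) {
        message(sprintf("epoch %3d  train %.6f  val %s", epoch, train_loss,
                        ifelse(is.na(val_loss), "-",
                               sprintf("%.6f", val_loss))))
      }
      if (!is.null(va)) {
        es <- es_update(es, val_loss, epoch, control$patience)
        if (es$best_epoch == epoch) {
          best <- list(params = model$params,
                       buffers = buffers_from_env(benv))
        }
        if (es$stop) {
          stopped_early <- TRUE
          break
        }
      } else {
        best <- list(params = model$params, buffers = buffers_from_env(benv))
        es$best_epoch <- epoch
      }
    }
  })

  model$params <- best$params
  model$buffers <- best$buffers
  history <- data.frame(epoch = seq_along(train_hist),
                        train_loss = train_hist, val_loss = val_hist)
  structure(list(model = model, config = config, control = control,
                 history = history, best_epoch = es$best_epoch,
                 stopped_early = stopped_early,
                 val = if (!is.null(val)) as_xy(val) else NULL),
            class = "lrr_unet")
}

#' Denoise segments with a fitted LRR-Unet
#'
#' Each segment is standardized by its own standard deviation, passed through
#' the network, and rescaled back, so predictions live on the input's
#' original scale.
#'
#' @param object A fitted `"lrr_unet"`.
#' @param newdata Numeric vector, matrix (segments x samples) or
#'   `"mixed_set"` of noisy input.
#' @param standardize Standardize-and-invert around the forward pass
#'   (disable only for inputs already on the training scale).
#' @param chunk Segments per forward pass.
#' @param ... Unused.
#' @return Matrix of denoised segments.
#' @export
predict.lrr_unet <- function(object, newdata, standardize = TRUE,
                             chunk = 128L, ...) {
  y <- if (inherits(newdata, "mixed_set")) newdata$y else newdata
  ym <- as_segment_matrix(y, "newdata")
  scales <- if (standardize) apply(ym, 1L, stats::sd) else rep(1, nrow(ym))
  if (any(scales == 0)) stop("constant segment cannot be standardized",
                             call. = FALSE)
  ys <- ym / scales
  out <- matrix(0, nrow(ym), ncol(ym))
  for (st in seq(1L, nrow(ym), by = chunk)) {
    en <- min(nrow(ym), st + chunk - 1L)
    fw <- lrr_unet_forward(object$model, ys[st:en, , drop = FALSE],
                           training = FALSE, keep_trajectory = FALSE)
    out[st:en, ] <- fw$output
  }
  out * scales
}

#' @export
print.lrr_unet <- function(x, ...) {
  cfg <- x$config
  cat("LRR-Unet: deep unfolded low-rank + sparse EEG denoiser\n")
  cat(sprintf("  stages (K): %d   output: %s   delta: %.2f\n",
              cfg$K, cfg$output_mode, cfg$delta))
  cat(sprintf("  Net-D: %s, parameters total: %d\n",
              if (cfg$netd$variant == "unet") {
                sprintf("1-D U-Net, depth %d, channels %s", cfg$netd$depth,
                        paste(cfg$netd$channels, collapse = "-"))
              } else {
                sprintf("plain CNN, %d layers x %d channels",
                        cfg$netd$cnn_layers,
                        cfg$netd$cnn_channels %||% 16L)
              },
              n_params(x$model)))
  if (nrow(x$history) > 0) {
    cat(sprintf("  trained %d epoch(s); best epoch %d%s\n",
                nrow(x$history), x$best_epoch,
                if (x$stopped_early) " (stopped early)" else ""))
  }
  cat(sprintf("  rho per stage: %s\n",
              paste(sprintf("%.4f", coef(x)), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.lrr_unet <- function(object, ...) {
  h <- object$history
  out <- list(K = object$config$K, n_params = n_params(object$model),
              epochs_run = nrow(h), best_epoch = object$best_epoch,
              stopped_early = object$stopped_early,
              final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA,
              best_val_loss = if (nrow(h) && !all(is.na(h$val_loss))) {
                min(h$val_loss, na.rm = TRUE)
              } else NA,
              rho = coef(object))
  class(out) <- "summary.lrr_unet"
  out
}

#' @export
print.summary.lrr_unet <- function(x, ...) {
  cat(sprintf("LRR-Unet fit: K = %d, %d parameters\n", x$K, x$n_params))
  cat(sprintf("  epochs run: %d, best epoch: %d, stopped early: %s\n",
              x$epochs_run, x$best_epoch, x$stopped_early))
  cat(sprintf("  final train loss: %.6g, best val loss: %.6g\n",
              x$final_train_loss, x$best_val_loss))
  cat(sprintf("  learned step sizes rho: %s\n",
              paste(sprintf("%.4f", x$rho), collapse = ", ")))
  invisible(x)
}

#' Learned per-stage step sizes
#'
#' The interpretable coefficients of the unfolded iteration: one learnable
#' scalar `rho_k` per stage, scaling the learned regularizer gradient in the
#' noise update.
#'
#' @param object A fitted `"lrr_unet"`.
#' @param ... Unused.
#' @return Named numeric vector `rho1..rhoK`.
#' @export
coef.lrr_unet <- function(object, ...) {
  nms <- paste0("rho", seq_len(object$config$K))
  vapply(nms, function(nm) as.numeric(object$model$params[[nm]]), numeric(1))
}

#' Noise residuals of a fitted LRR-Unet
#'
#' `y - x_hat` on the supplied (or stored validation) noisy segments: the
#' network's estimate of the artifact component.
#'
#' @param object A fitted `"lrr_unet"`.
#' @param newdata Optional noisy segments; defaults to the stored validation
#'   set.
#' @param ... Unused.
#' @return Matrix of residual segments.
#' @export
residuals.lrr_unet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$val)) {
      stop("no stored validation data; supply `newdata`", call. = FALSE)
    }
    newdata <- object$val$y
  }
  ym <- as_segment_matrix(if (inherits(newdata, "mixed_set")) newdata$y
                          else newdata)
  ym - predict(object, ym)
}

#' @export
fitted.lrr_unet <- function(object, ...) {
  if (is.null(object$val)) {
    stop("no stored validation data; use predict()", call. = FALSE)
  }
  predict(object, object$val$y)
}

#' Plot the training history of an LRR-Unet fit
#'
#' @param x A fitted `"lrr_unet"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lrr_unet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no training history to plot", call. = FALSE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "MSE loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' A single-file checkpoint holding the full parameter set, batch-norm
#' running statistics and the configuration; round-trippable with
#' [load_lrr_unet()].
#'
#' @param object A fitted `"lrr_unet"` (or bare `"lrr_unet_model"`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_lrr_unet <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_lrr_unet
#' @export
load_lrr_unet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("lrr_unet", "lrr_unet_model"))) {
    stop(sprintf("'%s' is not an LRR-Unet checkpoint", path), call. = FALSE)
  }
  obj
}
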