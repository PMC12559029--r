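# Benchmark and ablation runners: per-SNR metric curves, mean tables,
# K-sweep, U-Net-vs-CNN comparison, PSD reports, and file-level denoising.

# Short stable hash of an R object (polynomial rolling hash over its
# serialization, exact in double arithmetic), used to stamp benchmark tables
# with the configuration that produced them.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) {
    h <- (h * 31 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Resolve a "model" argument: a fitted lrr_unet, a bare model, or a plain
# function (y matrix) -> denoised matrix (used for identity/oracle baselines).
as_denoiser <- function(model) {
  if (inherits(model, "lrr_unet")) {
    return(function(y) predict(model, y))
  }
  if (inherits(model, "lrr_unet_model")) {
    return(function(y) lrr_unet_forward(model, y, keep_trajectory = FALSE)$output)
  }
  if (is.function(model)) return(model)
  stop("`model` must be a fitted lrr_unet, an lrr_unet_model, or a function",
       call. = FALSE)
}

#' Benchmark a denoiser on a per-SNR evaluation set
#'
#' Evaluates the four metrics per SNR level of an evaluation set built by
#' [build_eval_set()] and appends the unweighted mean row over SNR levels.
#'
#' @param model A fitted [lrr_unet()], an `"lrr_unet_model"`, or a function
#'   mapping a noisy segment matrix to a denoised one (e.g. `identity` or an
#'   oracle returning the clean reference).
#' @param eval_set A `"mixed_set"` containing an `snr` vector.
#' @param fs Sampling rate in Hz.
#' @param method Label for the `method` column.
#' @return Data frame of class `"benchmark_table"`, one row per SNR level
#'   plus a `"mean"` row; attributes carry the config hash.
#' @export
run_benchmark <- function(model, eval_set, fs = 256, method = "model") {
  stopifnot(inherits(eval_set, "mixed_set"))
  fun <- as_denoiser(model)
  x_hat <- fun(eval_set$y)
  levels <- sort(unique(eval_set$snr))
  if (length(levels) == 0L) stop("evaluation set has no SNR groups",
                                 call. = FALSE)
  rows <- lapply(levels, function(s) {
    idx <- which(eval_set$snr == s)
    ev <- evaluate_batch(x_hat[idx, , drop = FALSE],
                         eval_set$x[idx, , drop = FALSE], fs = fs)
    m <- ev[ev$segment == "mean", -1]
    cbind(method = method, snr_level = as.character(s), m)
  })
  tab <- do.call(rbind, rows)
  mean_row <- cbind(method = method, snr_level = "mean",
                    as.data.frame(t(colMeans(tab[, -(1:2)]))))
  out <- rbind(tab, mean_row)
  rownames(out) <- NULL
  attr(out, "config_hash") <- config_hash(if (inherits(model, "lrr_unet"))
    model$config else "function")
  class(out) <- c("benchmark_table", "data.frame")
  out
}

train_and_benchmark <- function(train_set, val_set, eval_set, config,
                                control, fs, method) {
  fit <- lrr_unet(train_set, val = val_set, config = config,
                  control = control)
  tab <- run_benchmark(fit, eval_set, fs = fs, method = method)
  list(fit = fit, table = tab)
}

#' Sweep the number of unfolded stages K
#'
#' Trains one model per `(K, seed)` combination under an otherwise identical
#' protocol and reports per-(K, seed) mean metrics plus the per-K median over
#' seeds. A failed run is recorded as `NA` rather than aborting the sweep.
#'
#' @param train_set,val_set,eval_set Mixed sets from [build_training_set()] /
#'   [build_eval_set()].
#' @param k_values Integer vector of stage counts.
#' @param seeds Integer vector of training seeds.
#' @param config Base [unfold_config()]; its `K` is overridden.
#' @param control Base [train_control()]; its `seed` is overridden.
#' @param fs Sampling rate in Hz.
#' @return Data frame with one row per `(K, seed)` and summary rows
#'   (`seed == "median"`) per K; attribute `config_hash` stamps the protocol.
#' @export
k_sweep <- function(train_set, val_set, eval_set, k_values = c(1L, 3L),
                    seeds = 0:2, config = unfold_config(),
                    control = train_control(), fs = 256) {
  stopifnot(length(k_values) >= 1L)
  rows <- list()
  for (K in k_values) {
    cfg <- config
    cfg$K <- as.integer(K)
    per_seed <- list()
    for (s in seeds) {
      ctl <- control
      ctl$seed <- as.integer(s)
      res <- tryCatch(
        train_and_benchmark(train_set, val_set, eval_set, cfg, ctl, fs,
                            method = sprintf("K=%d", K)),
        error = function(e) NULL)
      m <- if (is.null(res)) {
        data.frame(rrmse_t = NA_real_, rrmse_s = NA_real_, cc = NA_real_,
                   snr_db = NA_real_)
      } else {
        res$table[res$table$snr_level == "mean", c("rrmse_t", "rrmse_s",
                                                   "cc", "snr_db")]
      }
      per_seed[[length(per_seed) + 1L]] <-
        cbind(K = K, seed = as.character(s), m)
    }
    per_seed <- do.call(rbind, per_seed)
    med <- cbind(K = K, seed = "median",
                 as.data.frame(t(apply(per_seed[, -(1:2)], 2, stats::median,
                                       na.rm = TRUE))))
    rows[[length(rows) + 1L]] <- rbind(per_seed, med)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config_hash") <- config_hash(list(config, control, k_values))
  out
}

#' U-Net versus plain-CNN ablation
#'
#' Trains the unfolded model with its U-Net clean-signal estimator and the
#' `LRRnet` variant (Net-D replaced by a plain CNN of comparable parameter
#' count) under identical budgets and seeds, and reports paired mean metrics.
#'
#' @inheritParams k_sweep
#' @return Data frame with rows per (method, seed) and per-method median
#'   rows; attribute `config_hash` records both configurations.
#' @export
ablation_unet_vs_cnn <- function(train_set, val_set, eval_set, seeds = 0:2,
                                 config = unfold_config(),
                                 control = train_control(), fs = 256) {
  cnn_model <- build_lrrnet_variant(config, length = ncol(train_set$y))
  cnn_config <- cnn_model$config
  variants <- list(`LRR-Unet` = config, LRRnet = cnn_config)
  rows <- list()
  for (nm in names(variants)) {
    for (s in seeds) {
      ctl <- control
      ctl$seed <- as.integer(s)
      res <- tryCatch(
        train_and_benchmark(train_set, val_set, eval_set, variants[[nm]],
                            ctl, fs, method = nm),
        error = function(e) NULL)
      m <- if (is.null(res)) {
        data.frame(rrmse_t = NA_real_, rrmse_s = NA_real_, cc = NA_real_,
                   snr_db = NA_real_)
      } else {
        res$table[res$table$snr_level == "mean", c("rrmse_t", "rrmse_s",
                                                   "cc", "snr_db")]
      }
      rows[[length(rows) + 1L]] <- cbind(method = nm, seed = as.character(s),
                                         m)
    }
  }
  out <- do.call(rbind, rows)
  meds <- lapply(names(variants), function(nm) {
    sub <- out[out$method == nm, -(1:2)]
    cbind(method = nm, seed = "median",
          as.data.frame(t(apply(sub, 2, stats::median, na.rm = TRUE))))
  })
  out <- rbind(out, do.call(rbind, meds))
  rownames(out) <- NULL
  attr(out, "config_hash") <-
    vapply(variants, config_hash, character(1))
  out
}

#' Aligned PSD report of noisy, denoised and clean signals
#'
#' @param x_hat Denoised segment.
#' @param x Clean segment.
#' @param y Noisy segment.
#' @param fs Sampling rate in Hz.
#' @return Data frame with columns `freq`, `noisy`, `denoised`, `clean` on
#'   one shared frequency grid; plot with [plot_psd_report()].
#' @export
psd_report <- function(x_hat, x, y, fs = 256) {
  check_same_shape(x_hat, x)
  check_same_shape(x_hat, y, "x_hat", "y")
  pn <- welch_psd(y, fs)
  pd <- welch_psd(x_hat, fs)
  pc <- welch_psd(x, fs)
  data.frame(freq = pn$freq, noisy = pn$power, denoised = pd$power,
             clean = pc$power)
}

#' @rdname psd_report
#' @param report A data frame from [psd_report()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_psd_report <- function(report, ...) {
  graphics::matplot(report$freq, cbind(report$noisy, report$denoised,
                                       report$clean),
                    type = "l", lty = c(1, 1, 2), log = "y",
                    col = c("grey50", "firebrick", "black"),
                    xlab = "frequency (Hz)",
                    ylab = "PSD (units^2/Hz)", ...)
  graphics::legend("topright", c("noisy", "denoised", "clean"),
                   col = c("grey50", "firebrick", "black"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(report)
}

## ---- segment file I/O ------------------------------------------------------

#' Read / write segment matrices as delimited text
#'
#' Plain CSV with one segment per row and no header: the interchange format
#' of the command-line tools.
#'
#' @param path File path.
#' @return `read_segments()` returns a numeric matrix.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path),
                               call. = FALSE)
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' @rdname read_segments
#' @param x Numeric matrix (segments x samples) or vector.
#' @export
write_segments <- function(x, path) {
  utils::write.table(as_segment_matrix(x), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Denoise a segment file with a saved model
#'
#' Reads a CSV of segments, windows each row into non-overlapping frames of
#' the model's segment length (zero-padding the remainder and trimming it on
#' output), denoises with per-segment standardization inverted on output,
#' and writes the result. When a clean reference file is supplied, a
#' per-segment metric report is returned as well.
#'
#' @param model A fitted `"lrr_unet"` or a checkpoint path.
#' @param input_path,output_path CSV files (segments x samples).
#' @param clean_path Optional clean reference CSV of the same shape.
#' @param fs Sampling rate in Hz.
#' @return Invisibly, a list with `output_path` and, when a reference was
#'   given, the metric `report` from [evaluate_batch()].
#' @export
denoise_file <- function(model, input_path, output_path, clean_path = NULL,
                         fs = 256) {
  if (is.character(model)) model <- load_lrr_unet(model)
  y <- read_segments(input_path)
  L <- if (inherits(model, "lrr_unet")) model$model$length else model$length
  n_frames <- ceiling(ncol(y) / L)
  padded <- matrix(0, nrow(y), n_frames * L)
  padded[, seq_len(ncol(y))] <- y
  frames <- matrix(t(padded), ncol = L, byrow = TRUE)
  den <- matrix(0, nrow(frames), L)
  nonconst <- apply(frames, 1L, stats::sd) > 0
  if (any(nonconst)) {
    fun <- as_denoiser(model)
    den[nonconst, ] <- fun(frames[nonconst, , drop = FALSE])
  }
  out_padded <- matrix(t(den), nrow = nrow(y), byrow = TRUE)
  out <- out_padded[, seq_len(ncol(y)), drop = FALSE]
  write_segments(out, output_path)
  res <- list(output_path = output_path)
  if (!is.null(clean_path)) {
    x <- read_segments(clean_path)
    stopifnot(all(dim(x) == dim(y)))
    res$report <- evaluate_batch(out, x, fs = fs)
  }
  invisible(res)
}
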