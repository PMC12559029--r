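# Evaluation metrics: temporal and spectral relative RMSE, Pearson
# correlation, and SNR, plus Welch spectral estimation and batch aggregation.

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram, one-sided, density scaling
#' (signal-units^2/Hz). The defaults (window `min(256, length)`, 50% overlap)
#' are recorded in the returned object so paired spectra are always computed
#' with identical parameters.
#'
#' @param s Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_length Segment length of the averaged periodogram.
#' @param overlap Fractional overlap between windows in `[0, 1)`.
#' @return A list of class `"psd_estimate"` with `freq`, `power` and
#'   `method_params`.
#' @export
welch_psd <- function(s, fs = 256, window_length = min(256L, length(s)),
                      overlap = 0.5) {
  check_segments(s, "s")
  nw <- as.integer(window_length)
  if (length(s) < nw) {
    stop("signal shorter than the PSD window length", call. = FALSE)
  }
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, length(s) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1) / nw))   # periodic Hann
  U <- sum(w^2)
  nfreq <- nw %/% 2L + 1L
  acc <- numeric(nfreq)
  for (st in starts) {
    seg <- s[st:(st + nw - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (fs * U)
    half <- p[seq_len(nfreq)]
    # fold the negative frequencies onto the one-sided spectrum
    if (nw %% 2L == 0L) {
      half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    } else {
      half[2:nfreq] <- 2 * half[2:nfreq]
    }
    acc <- acc + half
  }
  structure(list(freq = (seq_len(nfreq) - 1) * fs / nw,
                 power = acc / length(starts),
                 method_params = list(estimator = "welch",
                                      window = "hann",
                                      window_length = nw,
                                      overlap = overlap, fs = fs)),
            class = "psd_estimate")
}

#' Temporal relative root-mean-square error
#'
#' `RMS(x_hat - x) / RMS(x)`.
#'
#' @param x_hat Denoised estimate.
#' @param x Clean reference.
#' @return Nonnegative scalar.
#' @export
rrmse_temporal <- function(x_hat, x) {
  check_segments(x_hat, "x_hat"); check_segments(x, "x")
  check_same_shape(x_hat, x)
  rx <- rms(x)
  if (rx == 0) stop("degenerate input: RMS(x) is zero", call. = FALSE)
  rms(x_hat - x) / rx
}

#' Spectral relative root-mean-square error
#'
#' `RMS(PSD(x_hat) - PSD(x)) / RMS(PSD(x))` with both spectra computed by
#' [welch_psd()] under identical parameters.
#'
#' @inheritParams rrmse_temporal
#' @param fs Sampling rate in Hz.
#' @param window_length,overlap Passed to [welch_psd()].
#' @return Nonnegative scalar.
#' @export
rrmse_spectral <- function(x_hat, x, fs = 256,
                           window_length = min(256L, length(x)),
                           overlap = 0.5) {
  check_same_shape(x_hat, x)
  p_hat <- welch_psd(x_hat, fs, window_length, overlap)$power
  p_ref <- welch_psd(x, fs, window_length, overlap)$power
  rr <- rms(p_ref)
  if (rr == 0) stop("degenerate input: reference PSD is zero", call. = FALSE)
  rms(p_hat - p_ref) / rr
}

#' Pearson correlation coefficient between estimate and reference
#'
#' @inheritParams rrmse_temporal
#' @return Scalar in `[-1, 1]`.
#' @export
corr_coef <- function(x_hat, x) {
  check_segments(x_hat, "x_hat"); check_segments(x, "x")
  check_same_shape(x_hat, x)
  if (stats::sd(x_hat) == 0 || stats::sd(x) == 0) {
    stop("degenerate input: constant signal has no defined correlation",
         call. = FALSE)
  }
  as.numeric(stats::cor(x_hat, x))
}

#' Signal-to-noise ratio in dB from powers
#'
#' `10 * log10(ps / pn)`. A zero noise power returns `Inf` (the documented
#' infinite-SNR sentinel), not an error.
#'
#' @param ps Signal power (> 0).
#' @param pn Noise power (>= 0).
#' @return SNR in dB.
#' @export
snr_db <- function(ps, pn) {
  check_scalar(ps, "ps", positive = TRUE)
  check_scalar(pn, "pn", nonnegative = TRUE)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' Signal-to-noise ratio in dB of an estimate against a reference
#'
#' Pairwise form with `Ps = mean(x^2)` and `Pn = mean((x_hat - x)^2)`.
#'
#' @inheritParams rrmse_temporal
#' @return SNR in dB (`Inf` for a perfect reconstruction).
#' @export
snr_db_pair <- function(x_hat, x) {
  check_same_shape(x_hat, x)
  snr_db(mean(x^2), mean((x_hat - x)^2))
}

#' Evaluate one denoised/clean pair on all four metrics
#'
#' A constant estimate (e.g. an all-zero output) has no defined correlation;
#' its `cc` entry is `NA` and is excluded from batch means.
#'
#' @inheritParams rrmse_spectral
#' @return One-row data frame with columns `rrmse_t`, `rrmse_s`, `cc`,
#'   `snr_db`.
#' @export
evaluate_pair <- function(x_hat, x, fs = 256) {
  cc <- if (stats::sd(x_hat) == 0 || stats::sd(x) == 0) NA_real_
        else corr_coef(x_hat, x)
  data.frame(rrmse_t = rrmse_temporal(x_hat, x),
             rrmse_s = rrmse_spectral(x_hat, x, fs = fs),
             cc = cc,
             snr_db = snr_db_pair(x_hat, x))
}

#' Evaluate a batch of pairs with mean aggregation
#'
#' @param x_hat Matrix of denoised segments (segments x samples).
#' @param x Matrix of clean references, same shape.
#' @param fs Sampling rate in Hz.
#' @return Data frame with one row per pair (`segment = 1..n`) plus a final
#'   `"mean"` row holding the arithmetic mean of each metric.
#' @export
evaluate_batch <- function(x_hat, x, fs = 256) {
  xh <- as_segment_matrix(x_hat, "x_hat")
  xr <- as_segment_matrix(x, "x")
  if (nrow(xh) == 0L) stop("empty batch", call. = FALSE)
  stopifnot(all(dim(xh) == dim(xr)))
  rows <- do.call(rbind, lapply(seq_len(nrow(xh)), function(i) {
    evaluate_pair(xh[i, ], xr[i, ], fs = fs)
  }))
  out <- cbind(segment = as.character(seq_len(nrow(xh))), rows,
               stringsAsFactors = FALSE)
  mean_row <- data.frame(segment = "mean", t(colMeans(rows, na.rm = TRUE)),
                         stringsAsFactors = FALSE)
  rbind(out, mean_row)
}
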