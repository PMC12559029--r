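# Synthetic EEG / EOG / EMG segment generators and SNR-controlled mixing.
#
# The generators emulate the structure of the public single-channel benchmark
# arrays this field trains on: clean EEG as band-structured oscillatory
# activity over a 1/f background, ocular artifacts as slow high-amplitude
# nonperiodic bumps, myogenic artifacts as short gated bursts of
# high-frequency noise.  Mixtures follow y = x + lambda * n with lambda solved
# from a target SNR.

#' Synthetic-signal configuration
#'
#' @param band_gains Named nonnegative amplitude gains for the canonical EEG
#'   bands delta (1-4 Hz), theta (4-8), alpha (8-13), beta (13-30) and gamma
#'   (30-80). The band with the largest gain dominates the spectrum of
#'   generated clean segments.
#' @param pink_exponent Spectral slope of the 1/f background (power falls as
#'   `f^-pink_exponent`).
#' @param pink_gain Amplitude of the 1/f background relative to the largest
#'   band gain; the background vanishes when all band gains are zero.
#' @param eog_rate Expected ocular events per segment (segments used as
#'   artifact sources always contain at least one event when the rate is
#'   positive).
#' @param eog_width_s Event half-width in seconds.
#' @param emg_burst_rate Expected myogenic bursts per segment.
#' @param emg_band Two-element `(low, high)` passband of the myogenic carrier
#'   noise in Hz; must sit inside `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @param length Segment length in samples.
#' @param seed Default seed used by the generators when none is supplied.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(band_gains = c(delta = 1, theta = 0.7, alpha = 1.2,
                                        beta = 0.5, gamma = 0.2),
                         pink_exponent = 1, pink_gain = 0.1,
                         eog_rate = 2, eog_width_s = 0.2,
                         emg_burst_rate = 3, emg_band = c(20, 120),
                         fs = 256, length = 512L, seed = 0L) {
  if (any(band_gains < 0)) stop("band gains must be >= 0", call. = FALSE)
  if (eog_rate < 0) stop("`eog_rate` must be >= 0", call. = FALSE)
  if (emg_burst_rate < 0) stop("`emg_burst_rate` must be >= 0", call. = FALSE)
  if (length(emg_band) != 2L || emg_band[1] <= 0 || emg_band[2] <= emg_band[1] ||
      emg_band[2] >= fs / 2) {
    stop("`emg_band` must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  if (is.null(names(band_gains)) || !all(names(band_gains) %in% bands)) {
    stop("`band_gains` must be named with canonical EEG bands", call. = FALSE)
  }
  structure(list(band_gains = band_gains, pink_exponent = pink_exponent,
                 pink_gain = pink_gain, eog_rate = eog_rate,
                 eog_width_s = eog_width_s, emg_burst_rate = emg_burst_rate,
                 emg_band = emg_band, fs = fs, length = as.integer(length),
                 seed = as.integer(seed)),
            class = "synth_config")
}

band_edges <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                   beta = c(13, 30), gamma = c(30, 80))

# Two-sided target amplitude response on the FFT grid of length L at rate fs.
clean_amplitude_response <- function(config) {
  L <- config$length
  fs <- config$fs
  f <- (seq_len(L) - 1) * fs / L
  f <- pmin(f, fs - f)                      # fold to the one-sided frequency
  p <- numeric(L)
  for (nm in names(config$band_gains)) {
    e <- band_edges[[nm]]
    p <- p + config$band_gains[[nm]]^2 * (f >= e[1] & f < e[2])
  }
  gmax <- max(config$band_gains)
  if (gmax > 0 && config$pink_gain > 0) {
    p <- p + (config$pink_gain * gmax)^2 * pmax(f, 1)^(-config$pink_exponent)
  }
  p[1] <- 0                                  # zero DC: zero-mean signals
  sqrt(p)
}

# Filter white Gaussian noise by an amplitude response via the FFT.
shaped_noise <- function(amp) {
  L <- length(amp)
  z <- stats::rnorm(L)
  Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / L
}

normalize_rms <- function(s) {
  r <- rms(s)
  if (r > 0) s / r else s
}

#' Generate clean-EEG-like segments
#'
#' Band-filtered Gaussian processes over a weak 1/f background, mean-centered
#' and (optionally) scaled to unit RMS. Identical `(config, seed)` yield
#' bitwise-identical output.
#'
#' @param config A [synth_config()].
#' @param n_segments Number of segments (>= 1).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param normalize Scale each segment to unit RMS.
#' @return Matrix `(n_segments x length)` with attribute `fs`.
#' @export
gen_clean <- function(config = synth_config(), n_segments, seed = config$seed,
                      normalize = TRUE) {
  n_segments <- check_n_segments(n_segments)
  amp <- clean_amplitude_response(config)
  out <- with_seed(seed, {
    t(vapply(seq_len(n_segments), function(i) {
      s <- shaped_noise(amp)
      s <- s - mean(s)
      if (normalize) s <- normalize_rms(s)
      s
    }, numeric(config$length)))
  })
  attr(out, "fs") <- config$fs
  out
}

check_n_segments <- function(n_segments) {
  if (!is.numeric(n_segments) || length(n_segments) != 1L || n_segments < 1) {
    stop("`n_segments` must be a positive integer", call. = FALSE)
  }
  as.integer(n_segments)
}

#' Generate ocular (EOG-like) artifact segments
#'
#' Smooth raised-cosine bumps at random times: low-frequency, high-amplitude,
#' nonperiodic events with at least 90% of their spectral energy below 5 Hz
#' at the default width.
#'
#' @inheritParams gen_clean
#' @return Matrix `(n_segments x length)` with attribute `fs`.
#' @export
gen_eog <- function(config = synth_config(), n_segments, seed = config$seed,
                    normalize = TRUE) {
  n_segments <- check_n_segments(n_segments)
  if (config$eog_rate < 0) stop("`eog_rate` must be >= 0", call. = FALSE)
  L <- config$length
  fs <- config$fs
  tt <- (seq_len(L) - 1) / fs
  out <- with_seed(seed, {
    t(vapply(seq_len(n_segments), function(i) {
      s <- numeric(L)
      if (config$eog_rate > 0) {
        # between one and a few events per segment: a 2-s window holds at
        # most a handful of blinks, and the cap keeps every segment
        # temporally sparse
        cap <- max(3L, ceiling(1.5 * config$eog_rate))
        n_ev <- min(cap, max(1L, stats::rpois(1L, config$eog_rate)))
        for (j in seq_len(n_ev)) {
          t0 <- stats::runif(1, 0, L / fs)
          w <- config$eog_width_s * stats::runif(1, 0.7, 1.1)
          a <- stats::runif(1, 0.5, 1.5)
          idx <- abs(tt - t0) <= w
          s[idx] <- s[idx] + a * 0.5 * (1 + cos(pi * (tt[idx] - t0) / w))
        }
        # single-polarity events are not centered: ocular bumps ride on a
        # zero baseline, which keeps them temporally sparse
        if (normalize) s <- normalize_rms(s)
      }
      s
    }, numeric(L)))
  })
  attr(out, "fs") <- config$fs
  out
}

# Tapered-cosine (Tukey) window of length n with taper fraction alpha.
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' Generate myogenic (EMG-like) artifact segments
#'
#' Band-passed Gaussian noise gated by short tapered windows: high-frequency,
#' short-burst interference whose support covers well under half the segment
#' at the default burst rate.
#'
#' @inheritParams gen_clean
#' @return Matrix `(n_segments x length)` with attribute `fs`.
#' @export
gen_emg <- function(config = synth_config(), n_segments, seed = config$seed,
                    normalize = TRUE) {
  n_segments <- check_n_segments(n_segments)
  L <- config$length
  fs <- config$fs
  lo <- config$emg_band[1]
  hi <- config$emg_band[2]
  f <- (seq_len(L) - 1) * fs / L
  f <- pmin(f, fs - f)
  amp <- as.numeric(f >= lo & f <= hi)
  amp[1] <- 0
  out <- with_seed(seed, {
    t(vapply(seq_len(n_segments), function(i) {
      s <- numeric(L)
      if (config$emg_burst_rate > 0) {
        carrier <- shaped_noise(amp)
        mask <- numeric(L)
        n_b <- max(1L, stats::rpois(1L, config$emg_burst_rate))
        for (j in seq_len(n_b)) {
          d <- stats::runif(1, 0.05, 0.2)              # burst duration, s
          nwin <- min(L, max(4L, round(d * fs)))
          start <- sample.int(L - nwin + 1L, 1L)
          idx <- start:(start + nwin - 1L)
          mask[idx] <- pmax(mask[idx], tukey_window(nwin, 0.5))
        }
        s <- carrier * mask
        s <- s - mean(s)
        if (normalize) s <- normalize_rms(s)
      }
      s
    }, numeric(L)))
  })
  attr(out, "fs") <- config$fs
  out
}

## ---- mixing ----------------------------------------------------------------

#' Solve the artifact scale for a target SNR
#'
#' Under the `"power"` convention (the SNR definition `10*log10(Ps/Pn)`),
#' `lambda = RMS(x) / (RMS(n) * 10^(snr_db/20))`; the `"rms_ratio"` dialect
#' used by the public benchmark protocol replaces the exponent by
#' `snr_db/10`.
#'
#' @param x Clean segment (numeric vector).
#' @param n Artifact segment at unit scale.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param convention `"power"` (default) or `"rms_ratio"`.
#' @return Positive scalar `lambda`.
#' @export
solve_lambda <- function(x, n, snr_db,
                         convention = c("power", "rms_ratio")) {
  convention <- match.arg(convention)
  check_segments(x, "x"); check_segments(n, "n")
  check_scalar(snr_db, "snr_db")
  rx <- rms(x); rn <- rms(n)
  if (rx == 0 || rn == 0) {
    stop("degenerate input: zero-RMS signal in `solve_lambda`", call. = FALSE)
  }
  expo <- if (convention == "power") snr_db / 20 else snr_db / 10
  rx / (rn * 10^expo)
}

#' Mix a clean segment with a scaled artifact at a target SNR
#'
#' Realizes `y = x + lambda * n` with `lambda` from [solve_lambda()]; the SNR
#' measured on `(x, lambda * n)` equals the request to floating-point
#' precision under the `"power"` convention.
#'
#' @inheritParams solve_lambda
#' @return A list of class `"mixed_triplet"` with fields `x`, `n`, `lam`,
#'   `y`, `snr_db`, `convention`.
#' @export
mix_segments <- function(x, n, snr_db,
                         convention = c("power", "rms_ratio")) {
  convention <- match.arg(convention)
  check_same_shape(x, n, "x", "n")
  lam <- solve_lambda(x, n, snr_db, convention)
  structure(list(x = x, n = n, lam = lam, y = x + lam * n,
                 snr_db = snr_db, convention = convention),
            class = "mixed_triplet")
}

#' Standardize a noisy/clean pair by the noisy segment's spread
#'
#' Both signals are divided by the standard deviation of `y` so the additive
#' mixture model is preserved and the clean target stays commensurate with
#' the network input.
#'
#' @param y Noisy segment.
#' @param x Clean segment.
#' @return List with `y_std`, `x_std` and the positive `scale`;
#'   `y_std * scale` recovers `y` exactly.
#' @export
standardize_pair <- function(y, x) {
  check_same_shape(y, x, "y", "x")
  scale <- stats::sd(y)
  if (!is.finite(scale) || scale == 0) {
    stop("degenerate input: `y` is constant, cannot standardize",
         call. = FALSE)
  }
  list(y_std = y / scale, x_std = x / scale, scale = scale)
}
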