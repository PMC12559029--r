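# Dataset construction: identity-disjoint splits of clean segments, the
# n-fold shuffled training protocol with uniformly drawn SNRs, and the
# deterministic per-integer-SNR evaluation grid.

#' Bundle clean and artifact segments with an identity-disjoint split
#'
#' Splits are taken over clean-segment identities (not over mixtures), so the
#' repeated shuffling of the training protocol can never leak a clean segment
#' across splits.
#'
#' @param clean Matrix of clean segments (segments x samples).
#' @param artifact Matrix of artifact segments (may have a different count).
#' @param artifact_kind `"eog"` or `"emg"`.
#' @param ratios Length-3 positive proportions for train/val/test (normalized
#'   internally).
#' @param seed Seed for the split shuffle.
#' @return A list of class `"dataset_bundle"` with `clean`, `artifact`,
#'   `artifact_kind` and index vectors `train_idx`, `val_idx`, `test_idx`.
#' @export
dataset_bundle <- function(clean, artifact, artifact_kind = c("emg", "eog"),
                           ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  artifact_kind <- match.arg(artifact_kind)
  clean <- as_segment_matrix(clean, "clean")
  artifact <- as_segment_matrix(artifact, "artifact")
  stopifnot(ncol(clean) == ncol(artifact), length(ratios) == 3L,
            all(ratios > 0))
  n <- nrow(clean)
  perm <- with_seed(seed, sample.int(n))
  ratios <- ratios / sum(ratios)
  n_train <- max(1L, floor(ratios[1] * n))
  n_val <- max(1L, floor(ratios[2] * n))
  if (n_train + n_val >= n) stop("not enough segments to split", call. = FALSE)
  structure(list(clean = clean, artifact = artifact,
                 artifact_kind = artifact_kind,
                 train_idx = sort(perm[seq_len(n_train)]),
                 val_idx = sort(perm[n_train + seq_len(n_val)]),
                 test_idx = sort(perm[(n_train + n_val + 1L):n]),
                 seed = as.integer(seed)),
            class = "dataset_bundle")
}

# Assemble a mixed set from parallel index/SNR vectors.
assemble_mixed_set <- function(bundle, clean_order, artifact_order, snrs,
                               convention) {
  n <- length(clean_order)
  L <- ncol(bundle$clean)
  x <- bundle$clean[clean_order, , drop = FALSE]
  nn <- bundle$artifact[artifact_order, , drop = FALSE]
  lam <- numeric(n)
  y <- matrix(0, n, L)
  for (i in seq_len(n)) {
    lam[i] <- solve_lambda(x[i, ], nn[i, ], snrs[i], convention)
    y[i, ] <- x[i, ] + lam[i] * nn[i, ]
  }
  structure(list(x = x, n = nn, y = y, lam = lam, snr = snrs,
                 clean_index = clean_order, artifact_index = artifact_order,
                 convention = convention),
            class = "mixed_set")
}

#' Build the shuffled training mixtures
#'
#' The training clean segments are shuffled `n_repeats` times and the
#' shuffles concatenated; each entry is paired with an artifact segment
#' (seeded artifact shuffle, then cyclic reuse) and mixed at an SNR drawn
#' uniformly from `snr_range`.
#'
#' @param bundle A [dataset_bundle()].
#' @param n_repeats Number of concatenated shuffles (one per nominal SNR
#'   level in the reference protocol).
#' @param snr_range Two-element range in dB.
#' @param convention SNR convention for [solve_lambda()].
#' @param seed Seed controlling shuffles and SNR draws.
#' @return A `"mixed_set"`: list with matrices `x`, `n`, `y` and vectors
#'   `lam`, `snr`, `clean_index`, `artifact_index`.
#' @export
build_training_set <- function(bundle, n_repeats = 10L,
                               snr_range = c(-7, 2),
                               convention = c("power", "rms_ratio"),
                               seed = 0L) {
  convention <- match.arg(convention)
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (length(bundle$train_idx) == 0L) stop("empty training split",
                                           call. = FALSE)
  with_seed(seed, {
    clean_order <- unlist(lapply(seq_len(n_repeats), function(r) {
      sample(bundle$train_idx)
    }), use.names = FALSE)
    n <- length(clean_order)
    art_perm <- sample.int(nrow(bundle$artifact))
    artifact_order <- art_perm[((seq_len(n) - 1L) %% length(art_perm)) + 1L]
    snrs <- stats::runif(n, snr_range[1], snr_range[2])
    assemble_mixed_set(bundle, clean_order, artifact_order, snrs, convention)
  })
}

#' Build the deterministic evaluation mixtures
#'
#' Every clean segment of the chosen split is mixed at each of the ten
#' integer SNRs -7..2 dB, with deterministic artifact pairing by index
#' cycling; output is grouped by SNR level and involves no randomness.
#'
#' @param bundle A [dataset_bundle()].
#' @param split `"val"` or `"test"`.
#' @param convention SNR convention for [solve_lambda()].
#' @return A `"mixed_set"` of size `10 * |split|`.
#' @export
build_eval_set <- function(bundle, split = c("test", "val"),
                           convention = c("power", "rms_ratio")) {
  split <- match.arg(split)
  convention <- match.arg(convention)
  stopifnot(inherits(bundle, "dataset_bundle"))
  idx <- if (split == "val") bundle$val_idx else bundle$test_idx
  if (length(idx) == 0L) stop("empty split", call. = FALSE)
  snr_levels <- -7:2
  clean_order <- rep(idx, times = length(snr_levels))
  snrs <- rep(snr_levels, each = length(idx))
  n_art <- nrow(bundle$artifact)
  artifact_order <- ((seq_along(clean_order) - 1L) %% n_art) + 1L
  assemble_mixed_set(bundle, clean_order, artifact_order, snrs, convention)
}

#' Generate a fully synthetic dataset bundle
#'
#' Convenience wrapper producing clean and artifact segments from the
#' synthetic generators and splitting them.
#'
#' @param n_clean,n_artifact Segment counts.
#' @param artifact_kind `"emg"` or `"eog"`.
#' @param config A [synth_config()].
#' @param ratios Split proportions.
#' @param seed Master seed (clean, artifact and split use derived offsets).
#' @return A `"dataset_bundle"`.
#' @export
synthetic_bundle <- function(n_clean = 500L, n_artifact = 400L,
                             artifact_kind = c("emg", "eog"),
                             config = synth_config(),
                             ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  artifact_kind <- match.arg(artifact_kind)
  clean <- gen_clean(config, n_clean, seed = seed + 1L)
  artifact <- if (artifact_kind == "emg") {
    gen_emg(config, n_artifact, seed = seed + 2L)
  } else {
    gen_eog(config, n_artifact, seed = seed + 2L)
  }
  dataset_bundle(clean, artifact, artifact_kind, ratios, seed = seed + 3L)
}
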