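# LRR-Unet: K unfolded stages of the penalized low-rank + sparse iteration,
# with learned modules replacing the proximal operators.
#
# Stage k receives (R_{k-1}, N_{k-1}) and computes
#   D_k = (R_{k-1} - N_{k-1}) + NetD(R_{k-1} - N_{k-1})        (U-Net, residual)
#   N_k = R_{k-1} + N_{k-1} - D - rho_k * g(N_{k-1}) + (R_{k-1} - D)
#         where g is a small conv stack standing in for the regularizer
#         gradient, and D is this stage's D_k (configurable to D_{k-1})
#   R_k = NetR(D_k + N_k)                                       (re-synthesis)
# with R_0 = y and N_0 = 0.  The default output is D_K.

#' Configuration of the clean-signal estimator (Net-D)
#'
#' @param depth Number of encoder levels (last level is the bottleneck and is
#'   not pooled).
#' @param channels Integer vector of channel widths per level, length `depth`.
#' @param kernel_size Odd convolution kernel size.
#' @param pool_factor Downsampling factor per level (only 2 is supported).
#' @param use_skips Keep the encoder-to-decoder skip connections (the ablation
#'   switch for a skip-free U-Net).
#' @param variant `"unet"` for the encoder-decoder, `"cnn"` for the plain
#'   stacked-convolution ablation network.
#' @param cnn_layers,cnn_channels Depth and width of the `"cnn"` variant.
#' @return A list of class `"netd_config"`.
#' @export
netd_config <- function(depth = 4L, channels = c(16L, 32L, 64L, 128L),
                        kernel_size = 3L, pool_factor = 2L, use_skips = TRUE,
                        variant = c("unet", "cnn"),
                        cnn_layers = 4L, cnn_channels = NULL) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  channels <- as.integer(channels)
  stopifnot(depth >= 2L, length(channels) == depth,
            kernel_size %% 2L == 1L, pool_factor == 2L)
  structure(list(depth = depth, channels = channels,
                 kernel_size = as.integer(kernel_size),
                 pool_factor = as.integer(pool_factor),
                 use_skips = isTRUE(use_skips), variant = variant,
                 cnn_layers = as.integer(cnn_layers),
                 cnn_channels = cnn_channels),
            class = "netd_config")
}

#' Configuration of the noise-gradient surrogate (Net-N)
#'
#' A stack of 1-D convolutions with ReLU between layers (final layer linear)
#' approximating the gradient of the noise regularizer.
#'
#' @param n_layers Total number of convolution layers (>= 1).
#' @param channels Hidden channel width.
#' @param kernel_size Odd kernel size.
#' @return A list of class `"netn_config"`.
#' @export
netn_config <- function(n_layers = 3L, channels = 16L, kernel_size = 3L) {
  stopifnot(n_layers >= 1L, kernel_size %% 2L == 1L)
  structure(list(n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size)),
            class = "netn_config")
}

#' Configuration of the raw-signal re-synthesis network (Net-R)
#'
#' @inheritParams netn_config
#' @return A list of class `"netr_config"`.
#' @export
netr_config <- function(n_layers = 2L, channels = 16L, kernel_size = 3L) {
  stopifnot(n_layers >= 1L, kernel_size %% 2L == 1L)
  structure(list(n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size)),
            class = "netr_config")
}

#' Configuration of the unfolded model
#'
#' @param K Number of unfolded stages (1..16). Three stages are the default,
#'   the depth at which the K-sweep saturates.
#' @param delta Fixed convex-combination weight of the noise update derivation;
#'   0.5 by construction, not learnable.
#' @param rho_init Initial value of each stage's learnable step-size scalar.
#' @param share_weights_across_stages Reuse one set of stage weights for all K
#'   stages (each stage keeps its own rho).
#' @param output_mode `"D_last"` (clean estimate of the final stage, default)
#'   or `"R_last"` (final re-synthesized signal).
#' @param strict_majorization Use the literal half-weighted derivation form of the
#'   noise update, `0.5*N + 0.5*(R - D) - rho*g(N)`, instead of the
#'   residual-enhanced form the network defines.
#' @param use_prev_D Feed the previous stage's clean estimate into the noise
#'   update instead of the current one (stage 1 falls back to `R_0`).
#' @param netd,netn,netr Subnetwork configurations.
#' @return A list of class `"unfold_config"`.
#' @export
unfold_config <- function(K = 3L, delta = 0.5, rho_init = 0.1,
                          share_weights_across_stages = FALSE,
                          output_mode = c("D_last", "R_last"),
                          strict_majorization = FALSE, use_prev_D = FALSE,
                          netd = netd_config(), netn = netn_config(),
                          netr = netr_config()) {
  output_mode <- match.arg(output_mode)
  K <- as.integer(K)
  if (K < 1L || K > 16L) stop("`K` must be in 1..16", call. = FALSE)
  if (!(delta > 0 && delta < 1)) stop("`delta` must be in (0,1)", call. = FALSE)
  structure(list(K = K, delta = delta, rho_init = rho_init,
                 share_weights_across_stages = isTRUE(share_weights_across_stages),
                 output_mode = output_mode, strict_majorization = isTRUE(strict_majorization),
                 use_prev_D = isTRUE(use_prev_D),
                 netd = netd, netn = netn, netr = netr),
            class = "unfold_config")
}

## ---- parameter initialization ---------------------------------------------

# Kaiming-uniform fan-in init for a conv (C_out, C_in, k); bias uniform in
# +/- 1/sqrt(fan_in), as is conventional for convolution layers.
init_conv <- function(cin, cout, k, zero = FALSE) {
  if (zero) {
    return(list(w = array(0, c(cout, cin, k)), b = numeric(cout)))
  }
  fan_in <- cin * k
  bw <- sqrt(6 / fan_in)
  bb <- 1 / sqrt(fan_in)
  list(w = array(stats::runif(cout * cin * k, -bw, bw), c(cout, cin, k)),
       b = stats::runif(cout, -bb, bb))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

netd_params <- function(cfg) {
  if (cfg$variant == "cnn") {
    ch <- cfg$cnn_channels
    if (is.null(ch)) ch <- 16L
    p <- list()
    cin <- 1L
    for (i in seq_len(cfg$cnn_layers)) {
      p[[paste0("conv", i)]] <- init_conv(cin, ch, cfg$kernel_size)
      p[[paste0("bn", i)]] <- init_bn(ch)
      cin <- ch
    }
    p$final <- init_conv(cin, 1L, cfg$kernel_size, zero = TRUE)
    return(p)
  }
  ch <- cfg$channels
  k <- cfg$kernel_size
  p <- list()
  cin <- 1L
  for (i in seq_len(cfg$depth)) {
    p[[paste0("enc", i)]] <- init_conv(cin, ch[i], k)
    p[[paste0("encbn", i)]] <- init_bn(ch[i])
    cin <- ch[i]
  }
  for (i in rev(seq_len(cfg$depth - 1L))) {
    p[[paste0("up", i)]] <- init_conv(cin, ch[i], 2L)   # transposed conv kernel
    dec_in <- if (cfg$use_skips) 2L * ch[i] else ch[i]
    p[[paste0("dec", i)]] <- init_conv(dec_in, ch[i], k)
    p[[paste0("decbn", i)]] <- init_bn(ch[i])
    cin <- ch[i]
  }
  # zero-initialized final projection: each stage starts as the identity of
  # the classical fixed point (D = R - N), so training refines the iteration
  # instead of first undoing a random perturbation
  p$final <- init_conv(cin, 1L, k, zero = TRUE)
  p
}

netn_params <- function(cfg) {
  p <- list()
  cin <- 1L
  for (i in seq_len(cfg$n_layers - 1L)) {
    p[[paste0("conv", i)]] <- init_conv(cin, cfg$channels, cfg$kernel_size)
    cin <- cfg$channels
  }
  p$final <- init_conv(cin, 1L, cfg$kernel_size)
  p
}

# Net-R carries an internal skip around its conv stack with a zero-initialized
# final projection, so it is the identity on D + N at initialization.
netr_params <- function(cfg) {
  p <- list()
  cin <- 1L
  for (i in seq_len(cfg$n_layers - 1L)) {
    p[[paste0("conv", i)]] <- init_conv(cin, cfg$channels, cfg$kernel_size)
    cin <- cfg$channels
  }
  p$final <- init_conv(cin, 1L, cfg$kernel_size, zero = TRUE)
  p
}

# Flatten a nested parameter list into a flat named list of arrays.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]]) && !is.null(names(p[[nm]])) &&
        all(vapply(p[[nm]], is.numeric, logical(1)) |
            vapply(p[[nm]], is.list, logical(1)))) {
      out <- c(out, flatten_params(p[[nm]], full))
    } else {
      out[[full]] <- p[[nm]]
    }
  }
  out
}

# Names of the batch-norm layers a Net-D holds, in wiring order.
netd_bn_names <- function(cfg) {
  if (cfg$variant == "cnn") {
    return(paste0("bn", seq_len(cfg$cnn_layers)))
  }
  c(paste0("encbn", seq_len(cfg$depth)),
    paste0("decbn", rev(seq_len(cfg$depth - 1L))))
}

netd_bn_channels <- function(cfg) {
  if (cfg$variant == "cnn") {
    ch <- cfg$cnn_channels
    if (is.null(ch)) ch <- 16L
    return(rep(ch, cfg$cnn_layers))
  }
  c(cfg$channels, rev(cfg$channels[seq_len(cfg$depth - 1L)]))
}

#' Build an LRR-Unet model with freshly initialized parameters
#'
#' @param config An [unfold_config()].
#' @param length Segment length in samples; must be divisible by
#'   `pool_factor^(depth-1)` of the Net-D configuration.
#' @param seed Integer seed controlling the initialization.
#' @return An object of class `"lrr_unet_model"` holding the flat parameter
#'   list, batch-norm running statistics, and the configuration.
#' @export
build_lrr_unet <- function(config = unfold_config(), length = 512L,
                           seed = 0L) {
  stopifnot(inherits(config, "unfold_config"))
  length <- as.integer(length)
  if (config$netd$variant == "unet") {
    down <- config$netd$pool_factor^(config$netd$depth - 1L)
    if (length %% down != 0L) {
      stop(sprintf(
        "segment length %d is not divisible by pool_factor^(depth-1) = %d",
        length, down), call. = FALSE)
    }
  }
  nstage <- if (config$share_weights_across_stages) 1L else config$K
  params <- with_seed(seed, {
    p <- list()
    for (k in seq_len(nstage)) {
      p[[paste0("stage", k)]] <- list(
        netd = netd_params(config$netd),
        netn = netn_params(config$netn),
        netr = netr_params(config$netr))
    }
    for (k in seq_len(config$K)) {
      p[[paste0("rho", k)]] <- config$rho_init
    }
    p
  })
  flat <- flatten_params(params)
  buffers <- list()
  for (k in seq_len(nstage)) {
    chs <- netd_bn_channels(config$netd)
    nms <- netd_bn_names(config$netd)
    for (j in seq_along(nms)) {
      buffers[[paste0("stage", k, ".netd.", nms[j])]] <-
        list(running_mean = numeric(chs[j]), running_var = rep(1, chs[j]))
    }
  }
  structure(list(params = flat, buffers = buffers, config = config,
                 length = length, seed = seed),
            class = "lrr_unet_model")
}

#' Count learnable parameters of a model
#'
#' @param model An `"lrr_unet_model"`.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

## ---- forward wiring --------------------------------------------------------

# Turn buffer lists into environments the BN op can mutate.
buffers_as_env <- function(buffers) {
  out <- new.env(parent = emptyenv())
  for (nm in names(buffers)) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- buffers[[nm]]$running_mean
    e$running_var <- buffers[[nm]]$running_var
    assign(nm, e, envir = out)
  }
  out
}

buffers_from_env <- function(env) {
  out <- list()
  for (nm in ls(env)) {
    e <- get(nm, envir = env)
    out[[nm]] <- list(running_mean = e$running_mean, running_var = e$running_var)
  }
  out
}

netd_forward_ad <- function(pn, prefix, x, cfg, benv, training) {
  bn <- function(nm, h) {
    ad_bn(h, pn[[paste0(prefix, ".", nm, ".gamma")]],
          pn[[paste0(prefix, ".", nm, ".beta")]],
          get(paste0(prefix, ".", nm), envir = benv), training = training)
  }
  cv <- function(nm, h) {
    ad_conv(h, pn[[paste0(prefix, ".", nm, ".w")]],
            pn[[paste0(prefix, ".", nm, ".b")]])
  }
  if (cfg$variant == "cnn") {
    h <- x
    for (i in seq_len(cfg$cnn_layers)) {
      h <- ad_relu(bn(paste0("bn", i), cv(paste0("conv", i), h)))
    }
    return(cv("final", h))
  }
  skips <- vector("list", cfg$depth - 1L)
  h <- x
  for (i in seq_len(cfg$depth)) {
    h <- ad_relu(bn(paste0("encbn", i), cv(paste0("enc", i), h)))
    if (i < cfg$depth) {
      skips[[i]] <- h
      h <- ad_maxpool(h)
    }
  }
  for (i in rev(seq_len(cfg$depth - 1L))) {
    h <- ad_upconv(h, pn[[paste0(prefix, ".up", i, ".w")]],
                   pn[[paste0(prefix, ".up", i, ".b")]])
    if (cfg$use_skips) h <- ad_concat(h, skips[[i]])
    h <- ad_relu(bn(paste0("decbn", i), cv(paste0("dec", i), h)))
  }
  cv("final", h)
}

conv_stack_forward_ad <- function(pn, prefix, x, n_layers) {
  h <- x
  for (i in seq_len(n_layers - 1L)) {
    h <- ad_relu(ad_conv(h, pn[[paste0(prefix, ".conv", i, ".w")]],
                         pn[[paste0(prefix, ".conv", i, ".b")]]))
  }
  ad_conv(h, pn[[paste0(prefix, ".final.w")]],
          pn[[paste0(prefix, ".final.b")]])
}

# Full tape-recorded forward pass.  `y` is an array (1, L, B).
# Returns the tape handles so callers can attach a loss and run backward.
unfold_forward_ad <- function(model, y, training = FALSE, benv = NULL) {
  cfg <- model$config
  tape <- ad_tape()
  pn <- lapply(model$params, function(v) ad_leaf(tape, v))
  if (is.null(benv)) benv <- buffers_as_env(model$buffers)

  R <- ad_leaf(tape, y)
  N <- ad_leaf(tape, array(0, dim(y)))
  D_prev <- R                       # stage-1 fallback when use_prev_D is set
  trajectory <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    sk <- if (cfg$share_weights_across_stages) "stage1" else paste0("stage", k)
    Z <- ad_sub(R, N)
    D <- ad_add(Z, netd_forward_ad(pn, paste0(sk, ".netd"), Z, cfg$netd,
                                   benv, training))
    if (any(!is.finite(ad_value(D)))) {
      stop(sprintf("non-finite values in Net-D output at stage %d", k),
           call. = FALSE)
    }
    D_used <- if (cfg$use_prev_D) D_prev else D
    g <- conv_stack_forward_ad(pn, paste0(sk, ".netn"), N, cfg$netn$n_layers)
    rho <- pn[[paste0("rho", k)]]
    step <- ad_smul(rho, g)
    if (cfg$strict_majorization) {
      N_new <- ad_sub(ad_add(ad_cmul(N, cfg$delta),
                             ad_cmul(ad_sub(R, D_used), 1 - cfg$delta)),
                      step)
    } else {
      N_new <- ad_sub(ad_add(N, ad_cmul(ad_sub(R, D_used), 2)), step)
    }
    if (any(!is.finite(ad_value(N_new)))) {
      stop(sprintf("non-finite values in Net-N output at stage %d", k),
           call. = FALSE)
    }
    DN <- ad_add(D, N_new)
    R_new <- ad_add(DN, conv_stack_forward_ad(pn, paste0(sk, ".netr"), DN,
                                              cfg$netr$n_layers))
    if (any(!is.finite(ad_value(R_new)))) {
      stop(sprintf("non-finite values in Net-R output at stage %d", k),
           call. = FALSE)
    }
    trajectory[[k]] <- list(R = ad_value(R_new), N = ad_value(N_new),
                            D = ad_value(D))
    D_prev <- D
    N <- N_new
    R <- R_new
    if (k == cfg$K) out_node <- if (cfg$output_mode == "D_last") D else R_new
  }
  list(tape = tape, output = out_node, param_nodes = pn,
       trajectory = trajectory, benv = benv)
}

#' Run the unfolded network forward
#'
#' Initializes `R_0 = y`, `N_0 = 0` and applies the K stages in order.
#'
#' @param model An `"lrr_unet_model"` from [build_lrr_unet()].
#' @param y Numeric vector (one segment) or matrix (segments x samples) of
#'   noisy input.
#' @param training Logical; use batch statistics (and update running ones) in
#'   batch-norm layers instead of the stored running estimates.
#' @param keep_trajectory Return the per-stage `(R_k, N_k, D_k)` states.
#' @return A list with `output` (matrix, segments x samples; the clean
#'   estimate `D_K` or re-synthesized `R_K` per the configured output mode)
#'   and, if requested, `trajectory` — a list of K per-stage states.
#' @export
lrr_unet_forward <- function(model, y, training = FALSE,
                             keep_trajectory = TRUE) {
  ym <- as_segment_matrix(y, "y")
  if (ncol(ym) != model$length) {
    stop(sprintf("input length %d does not match model length %d",
                 ncol(ym), model$length), call. = FALSE)
  }
  arr <- array(t(ym), c(1L, ncol(ym), nrow(ym)))
  fw <- unfold_forward_ad(model, arr, training = training)
  out <- ad_value(fw$output)
  outm <- t(matrix(out, ncol(ym), nrow(ym)))
  res <- list(output = outm)
  if (keep_trajectory) {
    res$trajectory <- lapply(fw$trajectory, function(st) {
      lapply(st, function(a) t(matrix(a, ncol(ym), nrow(ym))))
    })
  }
  res
}

#' Build the plain-CNN ablation variant (LRRnet)
#'
#' Returns a model with identical stage wiring in which the U-Net clean-signal
#' estimator is replaced by a stacked-convolution network of comparable size:
#' the hidden width is chosen so the variant's Net-D parameter count is as
#' close as possible to (and within a factor 2 of) the U-Net's.
#'
#' @param config An [unfold_config()] describing the U-Net reference model.
#' @param length Segment length in samples.
#' @param seed Initialization seed.
#' @return An `"lrr_unet_model"` whose Net-D is the plain CNN.
#' @export
build_lrrnet_variant <- function(config = unfold_config(), length = 512L,
                                 seed = 0L) {
  stopifnot(inherits(config, "unfold_config"))
  target <- sum(vapply(flatten_params(netd_params(config$netd)), length,
                       integer(1)))
  layers <- config$netd$cnn_layers
  count_for <- function(ch) {
    cfg <- config$netd
    cfg$variant <- "cnn"
    cfg$cnn_channels <- as.integer(ch)
    sum(vapply(flatten_params(netd_params(cfg)), length, integer(1)))
  }
  widths <- 2:512
  counts <- vapply(widths, count_for, numeric(1))
  best <- widths[which.min(abs(log(counts / target)))]
  netd <- config$netd
  netd$variant <- "cnn"
  netd$cnn_channels <- as.integer(best)
  cfg2 <- config
  cfg2$netd <- netd
  build_lrr_unet(cfg2, length = length, seed = seed)
}

#' Audit gradient flow through every learnable parameter
#'
#' Runs one forward/backward pass of the MSE loss on a (noisy, clean) batch
#' and reports the L2 norm of the gradient of each parameter tensor.
#'
#' @param model An `"lrr_unet_model"`.
#' @param y,x Matrices (segments x samples) of noisy input and clean target.
#' @return Named numeric vector of per-parameter gradient norms.
#' @export
gradient_audit <- function(model, y, x) {
  ym <- as_segment_matrix(y, "y")
  xm <- as_segment_matrix(x, "x")
  stopifnot(all(dim(ym) == dim(xm)))
  arr_y <- array(t(ym), c(1L, ncol(ym), nrow(ym)))
  arr_x <- array(t(xm), c(1L, ncol(xm), nrow(xm)))
  fw <- unfold_forward_ad(model, arr_y, training = TRUE)
  loss <- ad_mse(fw$output, arr_x)
  ids <- vapply(fw$param_nodes, function(nd) nd$id, integer(1))
  grads <- ad_backward(loss, ids)
  vapply(grads, function(g) if (is.null(g)) 0 else sqrt(sum(g^2)), numeric(1))
}
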