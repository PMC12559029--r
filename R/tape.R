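# Reverse-mode autodiff tape over (channel, time, batch) arrays.
#
# The unfolding network needs exact gradients of an MSE loss with respect to
# every convolution weight, batch-norm parameter and per-stage step-size
# scalar.  Rather than chaining hand-derived backward passes through the stage
# wiring (error prone across K stages), ops are recorded on a lightweight tape
# and differentiated by traversing it in reverse.  Every op stores a
# vector-Jacobian product closure; `ad_backward()` accumulates gradients into
# the requested leaf ids.  All values are dense 3-d arrays (C, L, B) except
# scalars (length-1) and the final loss.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ad_node <- function(tape, value, parents = integer(0), vjp = NULL) {
  # force the promises before claiming an id: `value` may itself build tape
  # nodes (ops composed inline), and those must precede this node in the
  # reverse-traversal order
  force(value); force(parents); force(vjp)
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- id
  tape$nodes[[id]] <- list(value = value, parents = parents, vjp = vjp)
  structure(list(id = id, tape = tape), class = "ad")
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_value <- function(x) x$tape$nodes[[x$id]]$value

is_ad <- function(x) inherits(x, "ad")

# Backward pass from a scalar loss node; returns a list mapping node id to
# accumulated gradient for the ids in `wanted`.
ad_backward <- function(loss, wanted) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  lv <- tape$nodes[[loss$id]]$value
  grads[[loss$id]] <- if (length(lv) == 1L) 1 else array(1, dim(lv))
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    if (is.null(nd$vjp)) next
    pg <- nd$vjp(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  out <- grads[wanted]
  names(out) <- names(wanted)
  out
}

## ---- elementwise ops -------------------------------------------------------

ad_add <- function(a, b) {
  ad_node(a$tape, ad_value(a) + ad_value(b), c(a$id, b$id),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$tape, ad_value(a) - ad_value(b), c(a$id, b$id),
          function(g) list(g, -g))
}

# multiply a node by a fixed scalar constant (not learnable)
ad_cmul <- function(a, const) {
  ad_node(a$tape, const * ad_value(a), a$id, function(g) list(const * g))
}

# multiply a node elementwise by a learnable scalar node (e.g. rho)
ad_smul <- function(s, x) {
  sv <- ad_value(s)
  xv <- ad_value(x)
  ad_node(x$tape, as.numeric(sv) * xv, c(s$id, x$id),
          function(g) list(sum(g * xv), as.numeric(sv) * g))
}

ad_relu <- function(x) {
  xv <- ad_value(x)
  mask <- xv > 0
  ad_node(x$tape, xv * mask, x$id, function(g) list(g * mask))
}

ad_concat <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(da[2] == db[2], da[3] == db[3])
  val <- array(0, c(da[1] + db[1], da[2], da[3]))
  val[seq_len(da[1]), , ] <- av
  val[da[1] + seq_len(db[1]), , ] <- bv
  ad_node(a$tape, val, c(a$id, b$id), function(g) {
    list(g[seq_len(da[1]), , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , drop = FALSE])
  })
}

## ---- convolutions ----------------------------------------------------------

ad_conv <- function(x, w, b) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  fw <- .conv1d_fw(xv, wv, bv)
  col <- fw$col
  ad_node(x$tape, fw$y, c(x$id, w$id, b$id), function(g) {
    bw <- .conv1d_bw(col, wv, g)
    list(bw$dx, bw$dw, as.numeric(bw$db))
  })
}

# transposed convolution, kernel 2 stride 2: doubles the time axis
ad_upconv <- function(x, w, b) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  d <- dim(xv)
  cin <- d[1]; L <- d[2]; B <- d[3]
  cout <- dim(wv)[1]
  xm <- matrix(xv, cin, L * B)
  y1 <- wv[, , 1, drop = FALSE]
  dim(y1) <- c(cout, cin)
  y2 <- wv[, , 2, drop = FALSE]
  dim(y2) <- c(cout, cin)
  o1 <- y1 %*% xm + bv
  o2 <- y2 %*% xm + bv
  val <- array(0, c(cout, 2L * L, B))
  val[, seq(1L, 2L * L, 2L), ] <- o1
  val[, seq(2L, 2L * L, 2L), ] <- o2
  ad_node(x$tape, val, c(x$id, w$id, b$id), function(g) {
    g1 <- matrix(g[, seq(1L, 2L * L, 2L), , drop = FALSE], cout, L * B)
    g2 <- matrix(g[, seq(2L, 2L * L, 2L), , drop = FALSE], cout, L * B)
    dw <- array(0, dim(wv))
    dw[, , 1] <- g1 %*% t(xm)
    dw[, , 2] <- g2 %*% t(xm)
    dxm <- crossprod(y1, g1) + crossprod(y2, g2)
    list(array(dxm, d), dw, rowSums(g1) + rowSums(g2))
  })
}

## ---- pooling and normalization --------------------------------------------

ad_maxpool <- function(x, factor = 2L) {
  xv <- ad_value(x)
  d <- dim(xv)
  stopifnot(factor == 2L, d[2] %% 2L == 0L)
  odd <- seq(1L, d[2], 2L); even <- seq(2L, d[2], 2L)
  xo <- xv[, odd, , drop = FALSE]
  xe <- xv[, even, , drop = FALSE]
  mask <- xo >= xe             # ties go to the earlier sample
  val <- xo * mask + xe * !mask
  ad_node(x$tape, val, x$id, function(g) {
    dx <- array(0, d)
    dx[, odd, ] <- g * mask
    dx[, even, ] <- g * !mask
    list(dx)
  })
}

# Batch normalization over (time x batch) per channel.  `state` is an
# environment carrying running_mean / running_var for inference mode.
ad_bn <- function(x, gamma, beta, state, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  xv <- ad_value(x)
  gv <- as.numeric(ad_value(gamma))
  bv <- as.numeric(ad_value(beta))
  d <- dim(xv)
  C <- d[1]; m <- d[2] * d[3]
  xm <- matrix(xv, C, m)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    # unbiased variance for the running estimate, as is conventional
    ub <- if (m > 1) va * m / (m - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    xc <- xm - mu
    va <- state$running_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * ivar
  val <- array(xhat * gv + bv, d)
  if (!training) {
    return(ad_node(x$tape, val, c(x$id, gamma$id, beta$id), function(g) {
      gm <- matrix(g, C, m)
      list(array(gm * gv * ivar, d), rowSums(gm * xhat), rowSums(gm))
    }))
  }
  ad_node(x$tape, val, c(x$id, gamma$id, beta$id), function(g) {
    gm <- matrix(g, C, m)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gv
    dx <- ivar * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(array(dx, d), dgamma, dbeta)
  })
}

## ---- loss ------------------------------------------------------------------

ad_mse <- function(pred, target) {
  pv <- ad_value(pred)
  res <- pv - target
  n <- length(pv)
  ad_node(pred$tape, mean(res * res), pred$id,
          function(g) list(as.numeric(g) * 2 * res / n))
}
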