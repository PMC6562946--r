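# Differentiable normalization layers (single-sample forms used inside the
# network).  Group normalization standardizes each group of channels over the
# sample's own spatial extent, so it is independent of batch composition.
# Batch normalization with the pipeline's batch size of one degenerates to
# per-channel spatial statistics in training mode; running averages are
# tracked in a mutable state environment for evaluation mode.

# x: (H, W, C); gamma/beta: length-C parameter nodes; channels are grouped
# contiguously, C divisible by groups.
ag_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv)
  C <- d[3]
  stopifnot(C %% groups == 0L)
  m <- d[1] * d[2] * (C %/% groups)
  xm <- xv
  dim(xm) <- c(m, groups)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v2 <- colMeans(xc * xc)
  istd <- 1 / sqrt(v2 + eps)
  xhat <- sweep(xc, 2, istd, "*")
  xhat_a <- xhat
  dim(xhat_a) <- d
  gv <- ag_value(gamma); bv <- ag_value(beta)
  y <- sweep(xhat_a, 3, gv, "*")
  y <- sweep(y, 3, bv, "+")
  ag_node(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(matrix(g * xhat_a, d[1] * d[2], C))
    dbeta <- colSums(matrix(g, d[1] * d[2], C))
    dxhat <- sweep(g, 3, gv, "*")
    dim(dxhat) <- c(m, groups)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dxm <- sweep(dxhat, 2, s1 / m) - sweep(xhat, 2, s2 / m, "*")
    dxm <- sweep(dxm, 2, istd, "*")
    dim(dxm) <- d
    list(dxm, dgamma, dbeta)
  })
}

# state: environment with $mean, $var running vectors (length C), $n updates
ag_batch_norm <- function(x, gamma, beta, state, training = TRUE,
                          eps = 1e-5, momentum = 0.1) {
  xv <- ag_value(x)
  d <- dim(xv)
  C <- d[3]
  gv <- ag_value(gamma); bv <- ag_value(beta)
  if (training) {
    out <- ag_group_norm(x, gamma, beta, groups = C, eps = eps)
    xm <- matrix(xv, d[1] * d[2], C)
    mu <- colMeans(xm)
    v2 <- colMeans(sweep(xm, 2, mu)^2)
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- v2
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v2
    }
    out
  } else {
    mu <- state$mean %||% numeric(C)
    v2 <- state$var %||% rep(1, C)
    istd <- 1 / sqrt(v2 + eps)
    scale <- gv * istd
    shift <- bv - mu * scale
    y <- sweep(sweep(xv, 3, scale, "*"), 3, shift, "+")
    ag_node(y, list(x, gamma, beta), function(g) {
      gm <- matrix(g, d[1] * d[2], C)
      xmm <- matrix(xv, d[1] * d[2], C)
      dgamma <- colSums(gm * sweep(xmm, 2, mu) %*% diag(istd, C))
      dbeta <- colSums(gm)
      dx <- sweep(g, 3, scale, "*")
      list(dx, dgamma, dbeta)
    })
  }
}
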