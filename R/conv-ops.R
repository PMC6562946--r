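# Convolution, pooling and resampling ops for the autodiff engine.
#
# Convolutions use im2col + BLAS matrix multiplication.  "Same" padding of
# dilation*(kernel-1)/2 is always applied, so stride-1 layers preserve the
# spatial grid regardless of dilation rate (rate-1 reduces exactly to a
# standard convolution).  Weights are stored as a (k*k*cin, cout) matrix whose
# row order is channel-fastest, then kernel row, then kernel column.

conv_out_extent <- function(n, k, stride, dilation) {
  p <- dilation * ((k - 1L) %/% 2L)
  eff <- dilation * (k - 1L) + 1L
  (n + 2L * p - eff) %/% stride + 1L
}

conv_im2col <- function(xp, k, stride, dilation, Ho, Wo, cin) {
  cols <- matrix(0, Ho * Wo, k * k * cin)
  j <- 0L
  for (kx in seq_len(k)) {
    ci <- seq.int((kx - 1L) * dilation + 1L, by = stride, length.out = Wo)
    for (ky in seq_len(k)) {
      j <- j + 1L
      ri <- seq.int((ky - 1L) * dilation + 1L, by = stride, length.out = Ho)
      blk <- xp[ri, ci, , drop = FALSE]
      dim(blk) <- c(Ho * Wo, cin)
      cols[, ((j - 1L) * cin + 1L):(j * cin)] <- blk
    }
  }
  cols
}

# x: (H, W, cin) node/array; w: (k*k*cin, cout) matrix node; b: length-cout node
ag_conv2d <- function(x, w, b, k, cin, cout, stride = 1L, dilation = 1L) {
  xv <- ag_value(x)
  d <- dim(xv)
  H <- d[1]; W <- d[2]
  stopifnot(d[3] == cin)
  p <- dilation * ((k - 1L) %/% 2L)
  eff <- dilation * (k - 1L) + 1L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - eff) %/% stride + 1L
  Wo <- (Wp - eff) %/% stride + 1L
  if (p > 0L) {
    xp <- array(0, c(Hp, Wp, cin))
    xp[(p + 1L):(p + H), (p + 1L):(p + W), ] <- xv
  } else xp <- xv
  cols <- conv_im2col(xp, k, stride, dilation, Ho, Wo, cin)
  wv <- ag_value(w); bv <- ag_value(b)
  y <- cols %*% wv
  y <- sweep(y, 2, bv, "+")
  dim(y) <- c(Ho, Wo, cout)
  ag_node(y, list(x, w, b), function(g) {
    gm <- g
    dim(gm) <- c(Ho * Wo, cout)
    dW <- crossprod(cols, gm)
    db <- colSums(gm)
    dcols <- tcrossprod(gm, wv)
    dxp <- array(0, c(Hp, Wp, cin))
    j <- 0L
    for (kx in seq_len(k)) {
      ci <- seq.int((kx - 1L) * dilation + 1L, by = stride, length.out = Wo)
      for (ky in seq_len(k)) {
        j <- j + 1L
        ri <- seq.int((ky - 1L) * dilation + 1L, by = stride, length.out = Ho)
        blk <- dcols[, ((j - 1L) * cin + 1L):(j * cin)]
        dim(blk) <- c(Ho, Wo, cin)
        dxp[ri, ci, ] <- dxp[ri, ci, ] + blk
      }
    }
    dx <- if (p > 0L) dxp[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE] else dxp
    list(dx, dW, db)
  })
}

# 2x2 max pooling, stride 2 (odd trailing row/column dropped)
ag_maxpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ro <- seq.int(1L, 2L * Ho, 2L); co <- seq.int(1L, 2L * Wo, 2L)
  a <- xv[ro, co, , drop = FALSE]
  b <- xv[ro + 1L, co, , drop = FALSE]
  cc <- xv[ro, co + 1L, , drop = FALSE]
  dd <- xv[ro + 1L, co + 1L, , drop = FALSE]
  v <- pmax(a, b, cc, dd)
  ag_node(v, list(x), function(g) {
    m1 <- a == v
    m2 <- (b == v) & !m1
    m3 <- (cc == v) & !(m1 | m2)
    m4 <- !(m1 | m2 | m3)
    dx <- array(0, d)
    dx[ro, co, ] <- g * m1
    dx[ro + 1L, co, ] <- g * m2
    dx[ro, co + 1L, ] <- g * m3
    dx[ro + 1L, co + 1L, ] <- g * m4
    list(dx)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  v <- xv[ri, ci, , drop = FALSE]
  ag_node(v, list(x), function(g) {
    odd_r <- seq.int(1L, 2L * d[1], 2L)
    odd_c <- seq.int(1L, 2L * d[2], 2L)
    g1 <- g[odd_r, , , drop = FALSE] + g[odd_r + 1L, , , drop = FALSE]
    dx <- g1[, odd_c, , drop = FALSE] + g1[, odd_c + 1L, , drop = FALSE]
    list(dx)
  })
}
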