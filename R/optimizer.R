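# Adaptive-moment optimizer with maximum-bound second-moment correction
# (amsgrad) and global gradient-norm clipping.

new_optimizer <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, clip_norm = 5) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$clip_norm <- clip_norm
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt$vhat <- lapply(params, function(p) p$value * 0)
  opt
}

optimizer_step <- function(opt, lr = NULL) {
  lr <- lr %||% opt$lr
  grads <- lapply(opt$params, function(p) p$grad)
  total_sq <- sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g * g), numeric(1)))
  gnorm <- sqrt(total_sq)
  scale <- if (is.finite(gnorm) && gnorm > opt$clip_norm) opt$clip_norm / gnorm else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    g <- g * scale
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    opt$vhat[[i]] <- pmax(opt$vhat[[i]], opt$v[[i]])
    p <- opt$params[[i]]
    p$value <- p$value - lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$vhat[[i]] / bc2) + opt$eps)
  }
  invisible(gnorm)
}
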