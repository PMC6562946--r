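# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Feature maps are plain R arrays in (H, W, C) layout (column-major, channel
# last).  A "node" is an environment holding $value and, while a tape is
# active, a $backward closure mapping the node's upstream gradient to the
# gradients of its parents.  Graphs are rebuilt every forward pass; parameter
# nodes persist across passes and accumulate gradients until zeroed.
#
# Recording order is a topological order, so reverse-mode sweeps the tape
# backwards once.  Only what the training pipeline needs is implemented.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_active <- function() !is.null(.ag$tape)

ag_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

ag_tape_end <- function() {
  t <- .ag$tape
  .ag$tape <- NULL
  invisible(t)
}

ag_record <- function(node) {
  t <- .ag$tape
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) length(t$nodes) <- 2L * length(t$nodes)
  t$nodes[[t$n]] <- node
  invisible(node)
}

# value: array/matrix/vector; parents: list of ag_node; backward: function(grad)
# returning a list of parent gradients (NULL entries allowed).
ag_node <- function(value, parents = NULL, backward = NULL, param = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$param <- param
  class(n) <- "ag_node"
  if (!is.null(backward) && ag_tape_active()) {
    n$parents <- parents
    n$backward <- backward
    ag_record(n)
  }
  n
}

ag_param <- function(value) ag_node(value, param = TRUE)

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$value else x

ag_accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Backpropagate from a scalar loss node through the active tape.
ag_backward <- function(loss, tape = .ag$tape) {
  stopifnot(ag_is_node(loss), !is.null(tape))
  loss$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pgrads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!is.null(p) && !is.null(pgrads[[j]])) ag_accumulate(p, pgrads[[j]])
    }
    if (!node$param) {
      # free intermediates eagerly
      node$grad <- NULL
      node$backward <- NULL
    }
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise / structural ops -------------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av + bv, list(a, b), function(g) list(g, g))
}

ag_scale <- function(a, s) {
  ag_node(ag_value(a) * s, list(a), function(g) list(g * s))
}

# weighted sum of scalar loss terms
ag_weighted_sum <- function(nodes, weights = rep(1, length(nodes))) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[[i]] * ag_value(nodes[[i]])
  ag_node(v, nodes, function(g) lapply(weights, function(w) g * w))
}

ag_relu <- function(a) {
  av <- ag_value(a)
  mask <- av > 0
  ag_node(av * mask, list(a), function(g) list(g * mask))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ag_value(a)))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_reshape <- function(a, dim) {
  av <- ag_value(a)
  odim <- dim(av) %||% length(av)
  v <- av
  dim(v) <- dim
  ag_node(v, list(a), function(g) { dim(g) <- odim; list(g) })
}

# gather flat indices (idx may be vector or matrix; output keeps idx's shape)
ag_gather <- function(a, idx) {
  av <- ag_value(a)
  v <- av[idx]
  dim(v) <- dim(idx)
  n <- length(av)
  odim <- dim(av) %||% length(av)
  ag_node(v, list(a), function(g) {
    z <- numeric(n)
    gs <- rowsum(as.vector(g), group = as.vector(idx))
    z[as.integer(rownames(gs))] <- gs
    dim(z) <- odim
    list(z)
  })
}

# concatenate (H, W, C_i) arrays along the channel axis
ag_concat_channels <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  d <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  v <- array(unlist(vals, use.names = FALSE), c(d[1], d[2], sum(chans)))
  ends <- cumsum(chans)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(v, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, , starts[i]:ends[i], drop = FALSE])
  })
}

ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# fully connected: x (n, d), w (d, k), b (k)
ag_linear <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  v <- xv %*% wv
  v <- sweep(v, 2, bv, "+")
  ag_node(v, list(x, w, b), function(g) {
    list(g %*% t(wv), crossprod(xv, g), colSums(g))
  })
}

# multiply by a constant sparse matrix S (Matrix::dgCMatrix): v = S %*% x
ag_sparse_mm <- function(S, x) {
  xv <- ag_value(x)
  v <- as.matrix(S %*% xv)
  ag_node(v, list(x), function(g) list(as.matrix(Matrix::crossprod(S, g))))
}

# stack 1-row (or equal-width) matrices vertically
ag_rbind <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  rows <- vapply(vals, nrow, numeric(1))
  ends <- cumsum(rows)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

## ---- losses ------------------------------------------------------------

# softmax cross-entropy over rows of logits (n, k); labels in 1..k; mean
ag_softmax_ce <- function(logits, labels) {
  lv <- ag_value(logits)
  n <- nrow(lv)
  m <- apply(lv, 1, max)
  e <- exp(lv - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels)
  v <- -mean(log(pmax(p[idx], 1e-12)))
  ag_node(v, list(logits), function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    list(g * d / n)
  })
}

# sigmoid binary cross-entropy with logits; mean over all elements
ag_bce_logits <- function(logits, targets) {
  lv <- ag_value(logits)
  s <- 1 / (1 + exp(-lv))
  n <- length(lv)
  v <- -sum(targets * log(pmax(s, 1e-12)) + (1 - targets) * log(pmax(1 - s, 1e-12))) / n
  ag_node(v, list(logits), function(g) list(g * (s - targets) / n))
}

# sum of smooth-L1 over (pred - target), scaled by `scale`
ag_smooth_l1_loss <- function(pred, target, scale = 1) {
  pv <- ag_value(pred)
  d <- pv - target
  a <- abs(d)
  v <- scale * sum(ifelse(a <= 1, 0.5 * d^2, a - 0.5))
  ag_node(v, list(pred), function(g) list(g * scale * clamp(d, -1, 1)))
}
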