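# shared fixtures built in code

# random partition-style label map: n rectangles placed in order, later
# placements occlude earlier ones (instances may shrink but not vanish
# entirely in the returned map)
rand_label_map <- function(H = 32L, W = 32L, n = 5L, seed = 1L) {
  set.seed(seed)
  lab <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    h <- sample(3:9, 1); w <- sample(3:9, 1)
    r <- sample(seq_len(H - h), 1); c <- sample(seq_len(W - w), 1)
    lab[r:(r + h - 1), c:(c + w - 1)] <- i
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- lab
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# finite-difference helper for matrix-valued parameters
finite_diff <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

toy_cached <- new.env(parent = emptyenv())
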