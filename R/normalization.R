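# Selectable feature normalization.
#
# Group normalization standardizes channel groups within each sample, so its
# output for a sample does not depend on what else is in the batch -- the
# property that keeps training stable when memory limits force batch size 1.
# Batch normalization pools statistics across the batch in training mode
# (and therefore does depend on batch composition), tracking running
# averages for evaluation mode; a frozen mode applies stored statistics in
# both modes.

#' Normalization specification
#'
#' @param kind `"group"` or `"batch"`.
#' @param num_groups channel groups for group normalization (default 32,
#'   reduced to the channel count when smaller; channels must divide evenly).
#' @param epsilon variance floor (default 1e-5).
#' @param affine apply learnable-style scale/shift? Here scale/shift default
#'   to identity (`gamma = 1`, `beta = 0`) unless supplied to
#'   [normalize()].
#' @param frozen for `"batch"`: use stored running statistics even in
#'   training mode (pretrained-statistics behaviour).
#' @return Object of class `norm_spec`.
#' @export
norm_spec <- function(kind = c("group", "batch"), num_groups = 32L,
                      epsilon = 1e-5, affine = TRUE, frozen = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, num_groups = as.integer(num_groups),
                 epsilon = epsilon, affine = affine, frozen = frozen),
            class = "norm_spec")
}

#' Fresh running-statistics state for batch normalization
#'
#' @return Environment with `mean`/`var` slots, filled on first training
#'   call.
#' @export
norm_state <- function() new.env(parent = emptyenv())

#' Normalize a batch of feature maps
#'
#' @param x a batch: list of (H, W, C) arrays, or a single (H, W, C) array
#'   (treated as batch size 1).
#' @param spec a [norm_spec()].
#' @param mode `"train"` or `"eval"`.
#' @param state running-statistics environment (see [norm_state()]); required
#'   for batch normalization in eval/frozen mode, updated in train mode.
#' @param gamma,beta optional per-channel scale/shift vectors.
#' @param momentum running-average update weight for batch statistics.
#' @return Normalized batch in the same container as the input.
#' @export
normalize <- function(x, spec, mode = c("train", "eval"), state = NULL,
                      gamma = NULL, beta = NULL, momentum = 0.1) {
  stopifnot(inherits(spec, "norm_spec"))
  mode <- match.arg(mode)
  single <- !is.list(x)
  batch <- if (single) list(x) else x
  C <- dim(batch[[1]])[3]
  gamma <- gamma %||% rep(1, C)
  beta <- beta %||% numeric(C)
  eps <- spec$epsilon
  out <- if (spec$kind == "group") {
    groups <- min(spec$num_groups, C)
    if (C %% groups != 0L)
      stopf("channels (%d) not divisible by num_groups (%d)", C, groups)
    lapply(batch, function(s) {
      d <- dim(s)
      m <- d[1] * d[2] * (C %/% groups)
      xm <- s; dim(xm) <- c(m, groups)
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc * xc)
      xh <- sweep(xc, 2, 1 / sqrt(v + eps), "*")
      dim(xh) <- d
      sweep(sweep(xh, 3, gamma, "*"), 3, beta, "+")
    })
  } else {
    use_running <- mode == "eval" || spec$frozen
    if (use_running) {
      if (is.null(state) || is.null(state$mean))
        stopf("batch normalization in eval/frozen mode needs tracked statistics")
      mu <- state$mean; v <- state$var
    } else {
      pool <- do.call(rbind, lapply(batch, function(s)
        matrix(s, dim(s)[1] * dim(s)[2], C)))
      mu <- colMeans(pool)
      v <- colMeans(sweep(pool, 2, mu)^2)
      if (!is.null(state)) {
        if (is.null(state$mean)) { state$mean <- mu; state$var <- v }
        else {
          state$mean <- (1 - momentum) * state$mean + momentum * mu
          state$var <- (1 - momentum) * state$var + momentum * v
        }
      }
    }
    scale <- gamma / sqrt(v + eps)
    shift <- beta - mu * scale
    lapply(batch, function(s) sweep(sweep(s, 3, scale, "*"), 3, shift, "+"))
  }
  if (single) out[[1]] else out
}
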