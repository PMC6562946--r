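# Multi-path dilated residual backbone (D-ResNet family).
#
# A multi-path block is a bottleneck residual block whose middle 3x3 stage is
# replaced by parallel dilated 3x3 convolutions (default expansion rates 1,
# 2, 5) merged by channel concatenation (or summation) before the restoring
# 1x1 convolution.  The rate-1 path plus the shortcut reproduces an ordinary
# bottleneck residual block exactly.  Later stages keep the spatial grid and
# widen their receptive field through stage-level dilation instead of
# striding, so small-object detail survives into the deepest stage.

## ---- parameterized layers ----------------------------------------------

new_conv_layer <- function(k, cin, cout, stride = 1L, dilation = 1L,
                           init = c("he", "zero")) {
  init <- match.arg(init)
  wm <- if (init == "zero") matrix(0, k * k * cin, cout)
        else matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                    k * k * cin, cout)
  list(type = "conv", w = ag_param(wm), b = ag_param(numeric(cout)),
       k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), dilation = as.integer(dilation))
}

conv_fwd <- function(l, x) {
  ag_conv2d(x, l$w, l$b, l$k, l$cin, l$cout, l$stride, l$dilation)
}

new_norm_layer <- function(kind, channels, num_groups = 32L, zero_scale = FALSE) {
  groups <- min(num_groups, channels)
  while (channels %% groups != 0L) groups <- groups - 1L
  list(type = "norm", kind = kind,
       gamma = ag_param(if (zero_scale) numeric(channels) else rep(1, channels)),
       beta = ag_param(numeric(channels)),
       groups = as.integer(groups), state = new.env(parent = emptyenv()))
}

norm_fwd <- function(l, x, training = TRUE) {
  if (l$kind == "group") ag_group_norm(x, l$gamma, l$beta, l$groups)
  else ag_batch_norm(x, l$gamma, l$beta, l$state, training = training)
}

new_linear_layer <- function(din, dout, init = c("he", "zero")) {
  init <- match.arg(init)
  wm <- if (init == "zero") matrix(0, din, dout)
        else matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
  list(type = "linear", w = ag_param(wm), b = ag_param(numeric(dout)),
       din = din, dout = dout)
}

linear_fwd <- function(l, x) ag_linear(x, l$w, l$b)

# collect ag_param nodes from a nested layer structure
collect_params <- function(x) {
  if (ag_is_node(x)) return(if (isTRUE(x$param)) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

## ---- multi-path block ----------------------------------------------------

#' Specification of one multi-path dilated residual block
#'
#' @param in_channels,out_channels block input/output channel counts.
#' @param bottleneck_channels width of the reduced bottleneck (each parallel
#'   path runs at this width).
#' @param rates ordered expansion rates of the parallel 3x3 paths (default
#'   `c(1, 2, 5)`); must contain 1 so the leftmost path plus the shortcut is
#'   exactly an ordinary residual block.
#' @param merge `"concat"` (channel concatenation, default) or `"sum"`.
#' @param normalization `"group"` or `"batch"`.
#' @param stride block entry stride (applied in the reducing 1x1 convolution
#'   and the projection shortcut).
#' @param dilation stage-level dilation multiplying every path's rate (used
#'   by later backbone stages in lieu of striding).
#' @param shortcut `"auto"` (projection when shape changes), `"identity"`, or
#'   `"projection"`. Requesting an identity shortcut with mismatched
#'   input/output channels is a configuration error.
#' @return Object of class `mp_block_spec`.
#' @export
multipath_block_spec <- function(in_channels, bottleneck_channels, out_channels,
                                 rates = c(1L, 2L, 5L),
                                 merge = c("concat", "sum"),
                                 normalization = c("group", "batch"),
                                 stride = 1L, dilation = 1L,
                                 shortcut = c("auto", "identity", "projection")) {
  merge <- match.arg(merge)
  normalization <- match.arg(normalization)
  shortcut <- match.arg(shortcut)
  if (length(rates) == 0L) stopf("`rates` must be non-empty")
  if (!1L %in% rates) stopf("`rates` must contain 1 (the standard-convolution path)")
  needs_proj <- in_channels != out_channels || stride != 1L
  if (shortcut == "identity" && needs_proj)
    stopf("identity shortcut requires out_channels == in_channels and stride 1; use a projection shortcut")
  if (shortcut == "auto") shortcut <- if (needs_proj) "projection" else "identity"
  structure(list(in_channels = as.integer(in_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 out_channels = as.integer(out_channels),
                 rates = as.integer(rates), merge = merge,
                 normalization = normalization, stride = as.integer(stride),
                 dilation = as.integer(dilation), shortcut = shortcut),
            class = "mp_block_spec")
}

#' Build a multi-path dilated residual block
#'
#' Assembles 1x1 reduce -> parallel dilated 3x3 convolutions (one per rate)
#' -> merge -> 1x1 restore -> shortcut addition, each convolution followed by
#' normalization (ReLU after reduce and each path, and after the final
#' addition). With stride 1 the output grid always equals the input grid:
#' dilation never shrinks the map.
#'
#' @param spec a [multipath_block_spec()].
#' @param init `"he"` (random, uses the current RNG state) or `"zero"`.
#' @return Object of class `mp_block`; run it with [block_forward()].
#' @export
build_block <- function(spec, init = "he") {
  stopifnot(inherits(spec, "mp_block_spec"))
  bn <- spec$bottleneck_channels
  reduce <- new_conv_layer(1L, spec$in_channels, bn, stride = spec$stride,
                           init = init)
  reduce_n <- new_norm_layer(spec$normalization, bn)
  paths <- lapply(spec$rates, function(r) {
    list(conv = new_conv_layer(3L, bn, bn, dilation = r * spec$dilation,
                               init = init),
         norm = new_norm_layer(spec$normalization, bn))
  })
  merged_channels <- if (spec$merge == "concat") bn * length(spec$rates) else bn
  restore <- new_conv_layer(1L, merged_channels, spec$out_channels, init = init)
  restore_n <- new_norm_layer(spec$normalization, spec$out_channels)
  proj <- NULL
  if (spec$shortcut == "projection") {
    proj <- list(conv = new_conv_layer(1L, spec$in_channels, spec$out_channels,
                                       stride = spec$stride, init = init),
                 norm = new_norm_layer(spec$normalization, spec$out_channels))
  }
  structure(list(spec = spec, reduce = reduce, reduce_n = reduce_n,
                 paths = paths, restore = restore, restore_n = restore_n,
                 proj = proj),
            class = "mp_block")
}

#' Run a multi-path block
#'
#' @param block an `mp_block` from [build_block()].
#' @param x input feature map: (H, W, in_channels) array (or internal
#'   autodiff node during training).
#' @param training training-mode flag (affects batch normalization).
#' @return Output feature map: array for array input, node for node input.
#' @export
block_forward <- function(block, x, training = TRUE) {
  was_node <- ag_is_node(x)
  if (!was_node) x <- ag_node(x)
  r <- ag_relu(norm_fwd(block$reduce_n, conv_fwd(block$reduce, x), training))
  outs <- lapply(block$paths, function(p)
    ag_relu(norm_fwd(p$norm, conv_fwd(p$conv, r), training)))
  merged <- if (block$spec$merge == "concat") {
    if (length(outs) == 1L) outs[[1]] else ag_concat_channels(outs)
  } else {
    m <- outs[[1]]
    for (o in outs[-1]) m <- ag_add(m, o)
    m
  }
  y <- norm_fwd(block$restore_n, conv_fwd(block$restore, merged), training)
  sc <- if (is.null(block$proj)) x
        else norm_fwd(block$proj$norm, conv_fwd(block$proj$conv, x), training)
  out <- ag_relu(ag_add(y, sc))
  if (was_node) out else ag_value(out)
}

## ---- backbone -------------------------------------------------------------

#' Backbone configuration
#'
#' Describes a D-ResNet-style backbone: a stem (optional 2x2 stride-2 max
#' pooling "down sampling layer" plus a 3x3 convolution) followed by stages
#' of multi-path blocks. Later stages replace striding with stage-level
#' dilation, so every stage after the last downsample shares one spatial
#' size. Output channels are capped (256 by default) so model size stays
#' bounded as depth grows.
#'
#' @param stem list with `pool` (logical), `channels`, `conv_stride`; or
#'   `NULL` for no stem.
#' @param stages list of per-stage lists with `blocks`, `bottleneck`,
#'   `channels`, `stride` (entry stride of the first block), `dilation`
#'   (stage-level rate multiplier).
#' @param rates,merge,normalization block settings shared by all stages (see
#'   [multipath_block_spec()]).
#' @param channel_cap maximum output channels of any convolution.
#' @param declared_depth optional declared weight-layer count; checked
#'   against [count_weight_layers()].
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(stem = list(pool = TRUE, channels = 64L, conv_stride = 2L),
                            stages = list(),
                            rates = c(1L, 2L, 5L),
                            merge = "concat", normalization = "group",
                            channel_cap = 256L, declared_depth = NULL) {
  cfg <- structure(list(stem = stem, stages = stages, rates = as.integer(rates),
                        merge = merge, normalization = normalization,
                        channel_cap = as.integer(channel_cap),
                        declared_depth = declared_depth),
                   class = "backbone_config")
  chans <- c(if (!is.null(stem)) stem$channels,
             unlist(lapply(stages, function(s) c(s$channels, s$bottleneck))))
  if (length(chans) && max(chans) > channel_cap)
    stopf("stage channels exceed the channel cap (%d)", channel_cap)
  if (!is.null(declared_depth)) {
    got <- count_weight_layers(cfg)
    if (got != declared_depth)
      stopf("declared depth %d but counted %d weight layers", declared_depth, got)
  }
  cfg
}

#' Count weight layers of a backbone configuration
#'
#' Depth is counted the way residual networks are conventionally named: the
#' stem convolution plus, per block, the reducing 1x1, one layer for the
#' (parallel) dilated 3x3 stage, and the restoring 1x1. Parallel paths count
#' once -- they add width, not depth -- and projection shortcuts and pooling
#' are not counted.
#'
#' @param config a [backbone_config()].
#' @return Integer weight-layer count.
#' @export
count_weight_layers <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  stem <- if (!is.null(config$stem)) 1L else 0L
  stem + 3L * sum(vapply(config$stages, function(s) as.integer(s$blocks),
                         integer(1)))
}

#' Build a backbone from a configuration
#'
#' @param config a [backbone_config()].
#' @param in_channels input image channels (default 3).
#' @param init `"he"` or `"zero"` weight initialization.
#' @return Object of class `backbone`; run with [backbone_forward()].
#' @export
build_backbone <- function(config, in_channels = 3L, init = "he") {
  stopifnot(inherits(config, "backbone_config"))
  stem <- NULL
  cur <- in_channels
  if (!is.null(config$stem)) {
    stem <- list(pool = isTRUE(config$stem$pool),
                 conv = new_conv_layer(3L, in_channels, config$stem$channels,
                                       stride = config$stem$conv_stride,
                                       init = init),
                 norm = new_norm_layer(config$normalization,
                                       config$stem$channels))
    cur <- config$stem$channels
  }
  stages <- list()
  for (si in seq_along(config$stages)) {
    s <- config$stages[[si]]
    blocks <- list()
    for (bi in seq_len(s$blocks)) {
      spec <- multipath_block_spec(
        in_channels = cur, bottleneck_channels = s$bottleneck,
        out_channels = s$channels, rates = config$rates,
        merge = config$merge, normalization = config$normalization,
        stride = if (bi == 1L) (s$stride %||% 1L) else 1L,
        dilation = s$dilation %||% 1L)
      blocks[[bi]] <- build_block(spec, init = init)
      cur <- s$channels
    }
    stages[[si]] <- blocks
  }
  structure(list(config = config, stem = stem, stages = stages,
                 out_channels = vapply(config$stages,
                                       function(s) as.integer(s$channels),
                                       integer(1))),
            class = "backbone")
}

#' Run a backbone over an image
#'
#' @param backbone a [build_backbone()] result.
#' @param x (H, W, C) input array (or internal node during training).
#' @param training training-mode flag.
#' @return List of per-stage feature maps, one per configured stage (arrays
#'   for array input, nodes for node input).
#' @export
backbone_forward <- function(backbone, x, training = TRUE) {
  was_node <- ag_is_node(x)
  if (!was_node) x <- ag_node(x)
  h <- x
  if (!is.null(backbone$stem)) {
    if (backbone$stem$pool) h <- ag_maxpool2(h)
    h <- ag_relu(norm_fwd(backbone$stem$norm,
                          conv_fwd(backbone$stem$conv, h), training))
  }
  outs <- vector("list", length(backbone$stages))
  for (si in seq_along(backbone$stages)) {
    for (blk in backbone$stages[[si]]) h <- block_forward(blk, h, training)
    outs[[si]] <- h
  }
  names(outs) <- paste0("stage", seq_along(outs) + 1L)
  if (was_node) outs else lapply(outs, ag_value)
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("backbone: %d stages, %d weight layers, channels (%s)\n",
              length(x$stages), count_weight_layers(x$config),
              paste(x$out_channels, collapse = ", ")))
  invisible(x)
}
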