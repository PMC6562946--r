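# Backbone presets.
#
# The deep preset follows the layout of a 50-layer bottleneck residual
# network: a stem (stride-2 max pooling + 3x3 stride-2 convolution, total
# stride 4), then four block stages. Stage 2 carries the last downsample
# (total output stride 8); stages 4 and 5 widen their receptive fields by
# stage-level dilation (2 and 4) instead of striding, so stages 3-5 share
# one spatial size and the deepest features keep small-object detail.
# Output channels stop growing at 256, bounding the model size.

#' Deep dilated residual backbone preset (64 weight layers)
#'
#' Stages of 3/4/6/8 multi-path blocks with output channels 64/128/256/256:
#' one stem convolution plus 21 blocks of 3 counted layers each = 64 weight
#' layers under the documented counting convention.
#'
#' @param normalization `"group"` (default) or `"batch"`.
#' @return A [backbone_config()].
#' @export
d_resnet64_config <- function(normalization = "group") {
  backbone_config(
    stem = list(pool = TRUE, channels = 64L, conv_stride = 2L),
    stages = list(
      list(blocks = 3L, bottleneck = 16L, channels = 64L,  stride = 2L, dilation = 1L),
      list(blocks = 4L, bottleneck = 32L, channels = 128L, stride = 1L, dilation = 1L),
      list(blocks = 6L, bottleneck = 64L, channels = 256L, stride = 1L, dilation = 2L),
      list(blocks = 8L, bottleneck = 64L, channels = 256L, stride = 1L, dilation = 4L)),
    rates = c(1L, 2L, 5L), merge = "concat", normalization = normalization,
    channel_cap = 256L, declared_depth = 64L)
}

#' Small dilated residual backbone preset (16 weight layers)
#'
#' Classification-scale variant: 1/1/1/2 blocks with channels 32/64/128/128.
#'
#' @inheritParams d_resnet64_config
#' @return A [backbone_config()].
#' @export
d_resnet16_config <- function(normalization = "group") {
  backbone_config(
    stem = list(pool = TRUE, channels = 32L, conv_stride = 2L),
    stages = list(
      list(blocks = 1L, bottleneck = 8L,  channels = 32L,  stride = 2L, dilation = 1L),
      list(blocks = 1L, bottleneck = 16L, channels = 64L,  stride = 1L, dilation = 1L),
      list(blocks = 1L, bottleneck = 32L, channels = 128L, stride = 1L, dilation = 2L),
      list(blocks = 2L, bottleneck = 32L, channels = 128L, stride = 1L, dilation = 4L)),
    rates = c(1L, 2L, 5L), merge = "concat", normalization = normalization,
    channel_cap = 256L, declared_depth = 16L)
}

#' Classical 50-layer bottleneck shape (single-rate blocks)
#'
#' A configuration shaped like the classical 50-layer residual network
#' (3/4/6/3 bottleneck blocks, single rate-1 path, sum merge); 49
#' convolutions under the counting convention (pooling carries no weights).
#' Used as a reference point for the layer-counting convention.
#'
#' @return A [backbone_config()].
#' @export
resnet50_shaped_config <- function() {
  backbone_config(
    stem = list(pool = TRUE, channels = 64L, conv_stride = 2L),
    stages = list(
      list(blocks = 3L, bottleneck = 64L,  channels = 256L,  stride = 1L, dilation = 1L),
      list(blocks = 4L, bottleneck = 128L, channels = 512L,  stride = 2L, dilation = 1L),
      list(blocks = 6L, bottleneck = 256L, channels = 1024L, stride = 2L, dilation = 1L),
      list(blocks = 3L, bottleneck = 512L, channels = 2048L, stride = 2L, dilation = 1L)),
    rates = c(1L), merge = "sum", normalization = "group",
    channel_cap = 2048L)
}

#' Desk-scale training configuration
#'
#' The staged schedule scaled to small from-scratch experiments: learning
#' rates 1e-3 / 1e-4 / 1e-5 (the conventional adaptive-moment starting rate
#' for small networks trained from random initialization), otherwise the
#' default regime (amsgrad, clip 5.0, batch size 1, group normalization).
#'
#' @param iterations iteration budget (default 200).
#' @param seed master seed.
#' @return A [train_config()].
#' @export
tiny_train_config <- function(iterations = 200L, seed = 0L) {
  train_config(learning_rates = c(1e-3, 1e-4, 1e-5),
               iterations = as.integer(iterations), seed = seed)
}

#' Easy fluorescence benchmark scene
#'
#' The desk-scale benchmark condition: 64 x 64 fluorescence scenes holding
#' 5-10 well-separated nuclei (radius 4-7 px, no overlap), indexed
#' deterministically from a base seed. Scenes 1..n form a training set;
#' disjoint index ranges give held-out sets.
#'
#' @param index scene index (distinct indices give independent scenes).
#' @param base_seed base seed (default 0).
#' @return A `synthetic_scene`.
#' @export
toy_fluorescence_scene <- function(index, base_seed = 0L) {
  n <- with_seed(derive_seed(base_seed, index, 1L), sample(5:10, 1))
  generate_scene(scene_spec(64L, 64L, n_nuclei = n, mode = "fluorescence",
                            radius_range = c(4, 7), max_overlap_fraction = 0,
                            min_instance_area = 21L,
                            seed = derive_seed(base_seed, index, 2L)))
}

#' Tiny desk-scale backbone preset
#'
#' One block per stage at 32 base channels, total output stride 4 (stem
#' stride 2, stage-2 stride 2, later stages dilated), sized for fast
#' experiments on small synthetic scenes.
#'
#' @inheritParams d_resnet64_config
#' @return A [backbone_config()].
#' @export
tiny_backbone_config <- function(normalization = "group") {
  backbone_config(
    stem = list(pool = TRUE, channels = 32L, conv_stride = 1L),
    stages = list(
      list(blocks = 1L, bottleneck = 8L,  channels = 32L, stride = 2L, dilation = 1L),
      list(blocks = 1L, bottleneck = 16L, channels = 64L, stride = 1L, dilation = 1L),
      list(blocks = 1L, bottleneck = 16L, channels = 64L, stride = 1L, dilation = 2L),
      list(blocks = 1L, bottleneck = 16L, channels = 64L, stride = 1L, dilation = 2L)),
    rates = c(1L, 2L, 5L), merge = "concat", normalization = normalization,
    channel_cap = 256L)
}
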