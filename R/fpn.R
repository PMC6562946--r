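# Feature-pyramid fusion over backbone stage outputs.
#
# Each stage is projected to a common channel width by a lateral 1x1
# convolution; a top-down path accumulates levels from deepest to shallowest;
# a 3x3 convolution smooths every fused level.  The dilated backbone's
# deepest stages keep one spatial size, so the top-down step between
# equal-resolution stages is a plain addition with no upsampling (the
# no-upsample rule); a 2:1 size ratio gets nearest-neighbour 2x upsampling,
# and anything else is a shape error.

#' Build a feature-pyramid fusion network
#'
#' @param stage_channels integer vector of backbone stage channel counts
#'   (shallow to deep); at least 2 stages.
#' @param pyramid_channels common channel width of all pyramid levels.
#' @param normalization norm kind used nowhere here (laterals and smoothers
#'   are plain convolutions, the standard pyramid design); reserved.
#' @param init `"he"` or `"zero"`.
#' @return Object of class `fpn`; apply with [fuse()].
#' @export
build_fpn <- function(stage_channels, pyramid_channels = 256L,
                      normalization = NULL, init = "he") {
  if (length(stage_channels) < 2L)
    stopf("a feature pyramid needs at least 2 stages")
  laterals <- lapply(stage_channels, function(ch)
    new_conv_layer(1L, ch, pyramid_channels, init = init))
  smoothers <- lapply(stage_channels, function(ch)
    new_conv_layer(3L, pyramid_channels, pyramid_channels, init = init))
  structure(list(laterals = laterals, smoothers = smoothers,
                 stage_channels = as.integer(stage_channels),
                 pyramid_channels = as.integer(pyramid_channels)),
            class = "fpn")
}

#' Fuse backbone stage outputs into pyramid levels
#'
#' Runs the lateral projections and the top-down accumulation. When the stage
#' above has the same spatial size the top-down step omits upsampling;
#' a 2:1 ratio is bridged by nearest-neighbour 2x upsampling.
#'
#' @param fpn a [build_fpn()] result.
#' @param stage_outputs list of stage feature maps ((H, W, C) arrays or
#'   nodes), shallow to deep, matching `fpn$stage_channels`.
#' @param smooth apply the per-level 3x3 smoothing convolutions (default
#'   TRUE); `FALSE` exposes the raw merged maps.
#' @return List of pyramid levels (same order as the stages), all at
#'   `pyramid_channels` channels; arrays for array inputs, nodes for node
#'   inputs.
#' @export
fuse <- function(fpn, stage_outputs, smooth = TRUE) {
  stopifnot(inherits(fpn, "fpn"))
  n <- length(stage_outputs)
  if (n != length(fpn$laterals))
    stopf("expected %d stage outputs, got %d", length(fpn$laterals), n)
  was_node <- any(vapply(stage_outputs, ag_is_node, logical(1)))
  stage_outputs <- lapply(stage_outputs, function(x)
    if (ag_is_node(x)) x else ag_node(x))
  lat <- lapply(seq_len(n), function(i)
    conv_fwd(fpn$laterals[[i]], stage_outputs[[i]]))
  levels <- vector("list", n)
  levels[[n]] <- lat[[n]]
  for (i in seq(n - 1L, 1L)) {
    upper <- levels[[i + 1L]]
    du <- dim(ag_value(upper)); dl <- dim(ag_value(lat[[i]]))
    if (all(du[1:2] == dl[1:2])) {
      merged <- ag_add(lat[[i]], upper)           # equal size: no upsampling
    } else if (all(dl[1:2] == 2L * du[1:2])) {
      merged <- ag_add(lat[[i]], ag_upsample2(upper))
    } else {
      stopf("stage sizes %dx%d and %dx%d are neither equal nor 2:1",
            dl[1], dl[2], du[1], du[2])
    }
    levels[[i]] <- merged
  }
  if (smooth)
    levels <- lapply(seq_len(n), function(i)
      conv_fwd(fpn$smoothers[[i]], levels[[i]]))
  names(levels) <- paste0("P", seq_len(n) + 1L)
  if (was_node) levels else lapply(levels, ag_value)
}
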