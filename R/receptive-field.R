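# Receptive-field arithmetic and pixel-coverage analysis for dilated
# convolution stacks.
#
# Stacked dilated convolutions that share an even expansion rate sample the
# input on a sparse lattice: some positions inside the nominal receptive
# field never contribute to the output (the gridding artifact).  Alternating
# rates (e.g. 1, 2, 5) removes the holes.  `coverage_map` demonstrates both
# regimes by exhaustive enumeration of tap-offset chains.

#' Specification of one dilated convolution layer
#'
#' @param kernel odd kernel size (default 3).
#' @param rate expansion (dilation) rate; rate 1 is a standard convolution.
#' @param stride stride (default 1).
#' @param out_channels declared output channels (bookkeeping only).
#' @return Object of class `dilated_conv_spec`.
#' @export
dilated_conv_spec <- function(kernel = 3L, rate = 1L, stride = 1L,
                              out_channels = NULL) {
  if (!is_count(kernel, 1L) || kernel %% 2L == 0L) stopf("`kernel` must be odd")
  if (!is_count(rate, 1L)) stopf("`rate` must be a positive integer")
  if (!is_count(stride, 1L)) stopf("`stride` must be a positive integer")
  structure(list(kernel = as.integer(kernel), rate = as.integer(rate),
                 stride = as.integer(stride), out_channels = out_channels),
            class = "dilated_conv_spec")
}

as_conv_stack <- function(stack) {
  if (inherits(stack, "dilated_conv_spec")) stack <- list(stack)
  stopifnot(length(stack) > 0L,
            all(vapply(stack, inherits, logical(1), "dilated_conv_spec")))
  stack
}

#' Receptive-field extent of a dilated convolution stack
#'
#' Closed-form effective extent (in input pixels, one axis) of the region
#' that can influence a single output unit:
#' `1 + sum_i (k_i - 1) * r_i * prod_{j<i} s_j`.
#'
#' @param stack list of [dilated_conv_spec()] (input-to-output order).
#' @return Extent in pixels (odd integer).
#' @examples
#' receptive_field(list(dilated_conv_spec(3, 2)))  # 5
#' @export
receptive_field <- function(stack) {
  stack <- as_conv_stack(stack)
  ext <- 1L
  jump <- 1L
  for (sp in stack) {
    ext <- ext + (sp$kernel - 1L) * sp$rate * jump
    jump <- jump * sp$stride
  }
  ext
}

#' Per-position contribution counts inside the receptive field
#'
#' Counts, for every input position, how many tap-offset chains through the
#' stack connect it to the center output unit, by exhaustive enumeration
#' (propagating counts layer by layer from the output back to the input).
#' Zero counts inside the receptive field are the gridding artifact of
#' stacked even-rate dilated convolutions; an alternating-rate stack such as
#' (1, 2, 5) has none.
#'
#' @param stack list of [dilated_conv_spec()] (input-to-output order).
#' @param grid_size odd extent of the returned square count grid; must be at
#'   least the receptive-field extent.
#' @return `grid_size` x `grid_size` integer matrix of contribution counts,
#'   centered on the output unit's projection.
#' @export
coverage_map <- function(stack, grid_size = NULL) {
  stack <- as_conv_stack(stack)
  rf <- receptive_field(stack)
  grid_size <- grid_size %||% rf
  if (grid_size < rf)
    stopf("grid_size %d is smaller than the receptive field (%d)", grid_size, rf)
  half <- (grid_size - 1L) %/% 2L
  size <- 2L * half + 1L
  counts <- matrix(0, size, size)
  center <- half + 1L
  counts[center, center] <- 1
  # walk output -> input; each layer spreads counts over its dilated taps
  for (i in rev(seq_along(stack))) {
    sp <- stack[[i]]
    offs <- (seq_len(sp$kernel) - (sp$kernel + 1L) / 2L) * sp$rate
    nz <- which(counts != 0, arr.ind = TRUE)
    new_counts <- matrix(0, size, size)
    for (k in seq_len(nrow(nz))) {
      r <- nz[k, 1]; cc <- nz[k, 2]; v <- counts[r, cc]
      # position of this unit in the layer-input frame
      rr <- center + (r - center) * sp$stride
      ccc <- center + (cc - center) * sp$stride
      tr <- rr + offs; tc <- ccc + offs
      if (any(tr < 1L | tr > size | tc < 1L | tc > size))
        stopf("grid_size %d too small during propagation", grid_size)
      new_counts[tr, tc] <- new_counts[tr, tc] + v
    }
    counts <- new_counts
  }
  counts
}
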