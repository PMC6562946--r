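# Reading and writing instance annotation layouts.
#
# The on-disk layout mirrors the per-image directory convention of public
# nucleus challenges: one image file plus a masks/ subdirectory holding one
# binary mask PNG per instance, listed in a plain-text manifest.  A label map
# can alternatively be stored as a single image: 16-bit grayscale TIFF, or a
# PNG whose red/green channels encode id = 256*R + G (PNG writers here are
# 8-bit per channel).

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  img
}

#' Write a scene as an instance layout directory
#'
#' Writes `root/image.png`, one binary mask PNG per instance under
#' `root/masks/`, and a plain-text `manifest.txt` listing the files (image
#' first, then masks in instance-id order).
#'
#' @param scene a `synthetic_scene`, or any list with an `image` (H x W x 3
#'   integer array, 0..255) and `labels` (integer label map).
#' @param root target directory.
#' @param overwrite overwrite an existing non-empty directory? An existing
#'   non-empty `root` is refused unless `TRUE`.
#' @return Invisibly, the manifest: character vector of relative file paths.
#' @export
write_instance_layout <- function(scene, root, overwrite = FALSE) {
  stopifnot(is.list(scene), !is.null(scene$image), !is.null(scene$labels))
  if (dir.exists(root) && length(dir(root, all.files = TRUE, no.. = TRUE)) > 0L) {
    if (!overwrite) stopf("directory '%s' exists and is not empty", root)
    unlink(file.path(root, c("image.png", "manifest.txt", "masks")),
           recursive = TRUE)
  }
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$image / 255, file.path(root, "image.png"))
  labels <- scene$labels
  ids <- sort(unique(labels[labels > 0]))
  mask_files <- character(0)
  for (i in ids) {
    fn <- sprintf("masks/mask_%04d.png", i)
    png::writePNG((labels == i) * 1, file.path(root, fn))
    mask_files <- c(mask_files, fn)
  }
  manifest <- c("image.png", mask_files)
  writeLines(manifest, file.path(root, "manifest.txt"))
  invisible(manifest)
}

#' Read an instance layout directory into a label map
#'
#' Merges the per-instance binary masks under `root/masks/` into one integer
#' label map. Masks are read in manifest order (falling back to sorted file
#' names); when two masks claim the same pixel the first-listed mask keeps it
#' and a warning is emitted.
#'
#' @param root directory written by [write_instance_layout()] (or following
#'   the same convention).
#' @return Integer label map (0 = background) with instance ids numbered in
#'   mask file order.
#' @export
read_instance_layout <- function(root) {
  img_files <- dir(root, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  if (length(img_files) == 0L) stopf("no image file found in '%s'", root)
  img <- read_image_file(file.path(root, img_files[1]))
  H <- dim(img)[1]; W <- dim(img)[2]
  mask_dir <- file.path(root, "masks")
  if (!dir.exists(mask_dir)) stopf("'%s' has no masks/ subdirectory", root)
  manifest_path <- file.path(root, "manifest.txt")
  if (file.exists(manifest_path)) {
    entries <- readLines(manifest_path)
    masks <- entries[startsWith(entries, "masks/")]
    masks <- file.path(root, masks)
  } else {
    masks <- sort(dir(mask_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE))
  }
  labels <- matrix(0L, H, W)
  clash <- FALSE
  for (k in seq_along(masks)) {
    m <- read_image_file(masks[k])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!all(dim(m) == c(H, W)))
      stopf("mask '%s' size %dx%d does not match image %dx%d",
            basename(masks[k]), nrow(m), ncol(m), H, W)
    fg <- m > 0.5
    taken <- fg & labels > 0L
    if (any(taken)) {
      clash <- TRUE
      fg <- fg & labels == 0L  # first-listed mask owns contested pixels
    }
    labels[fg] <- k
  }
  if (clash) warnf("overlapping masks detected; first-listed mask kept contested pixels")
  labels
}

#' Write a label map as a single image file
#'
#' `.tif`/`.tiff` paths store ids as 16-bit grayscale; `.png` paths store
#' `id = 256 * R + G` across the red and green 8-bit channels.
#'
#' @param labels integer label map.
#' @param path output file (`.png`, `.tif` or `.tiff`).
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(labels, path) {
  ext <- tolower(tools::file_ext(path))
  if (max(labels) > 65535L) stopf("label ids exceed 16-bit range")
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("writing TIFF requires the 'tiff' package")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    H <- nrow(labels); W <- ncol(labels)
    img <- array(0, c(H, W, 3))
    img[, , 1] <- (labels %/% 256L) / 255
    img[, , 2] <- (labels %% 256L) / 255
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path image file produced by [write_label_map()].
#' @return Integer label map.
#' @export
read_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- read_image_file(path)
  if (ext %in% c("tif", "tiff")) {
    m <- if (length(dim(img)) == 3L) img[, , 1] else img
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  } else {
    matrix(as.integer(round(img[, , 1] * 255)) * 256L +
           as.integer(round(img[, , 2] * 255)), dim(img)[1], dim(img)[2])
  }
}
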