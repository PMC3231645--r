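#' Leaf image container
#'
#' An RGB raster together with the known background color of the acquisition
#' board. Pixels are stored as an `H x W x 3` numeric array of 8-bit
#' intensities in `[0, 255]`; images are acquired as a single leaf lying on a
#' uniform near-white board, so the background color is metadata rather than
#' something to re-estimate.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @param background_rgb length-3 vector, the board color (default
#'   `c(250, 250, 250)`).
#' @param path optional source identifier.
#' @return An object of class `leaf_image`.
#' @export
leaf_image <- function(pixels, background_rgb = c(250, 250, 250), path = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (length(background_rgb) != 3 || any(background_rgb < 0) ||
      any(background_rgb > 255))
    stop("`background_rgb` must be 3 values in [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, background_rgb = as.numeric(background_rgb),
         path = path),
    class = "leaf_image"
  )
}

#' @export
print.leaf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<leaf_image %d x %d, background rgb(%s)%s>\n", d[1], d[2],
              paste(round(x$background_rgb), collapse = ","),
              if (is.null(x$path)) "" else paste0(", ", x$path)))
  invisible(x)
}

#' @export
dim.leaf_image <- function(x) dim(x$pixels)

#' Read a leaf image from a PNG file
#'
#' @param path PNG file path.
#' @param background_rgb board color metadata attached to the image.
#' @return A [leaf_image()].
#' @export
read_leaf_image <- function(path, background_rgb = c(250, 250, 250)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  leaf_image(round(px * 255), background_rgb = background_rgb, path = path)
}

#' Write a leaf image to a PNG file
#'
#' @param image a [leaf_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_leaf_image <- function(image, path) {
  stopifnot(inherits(image, "leaf_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Luminance channel of an RGB image
#'
#' Rec. 601 luma, `0.299 R + 0.587 G + 0.114 B`, rounded to integers in
#' `[0, 255]`; the single-channel input to edge detection and to gray-level
#' degradation.
#'
#' @param image a [leaf_image()] or an `H x W x 3` array.
#' @return An `H x W` numeric matrix.
#' @export
luminance <- function(image) {
  px <- if (inherits(image, "leaf_image")) image$pixels else image
  round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
}
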