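#' @useDynLib oedcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif predict sd setNames
NULL

# The RGB -> YCbCr transform: offset + (1/256) * A %*% rgb.  The chroma rows
# of A sum to exactly zero, so greys map to (Y, 128, 128).
.ycbcr_offset <- c(16, 128, 128)
.ycbcr_matrix <- matrix(c(
   65.738, 129.057,  25.064,
  -37.945, -74.494, 112.439,
  112.439, -94.154, -18.285
), nrow = 3, byrow = TRUE) / 256

.augmentation_kinds <- c("horizontal_flip", "vertical_flip", "rotate_180")

assert_image <- function(image, arg = "image", check_range = TRUE) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    abort(sprintf("`%s` must be a height x width x channel array", arg))
  }
  if (dim(image)[3] != 3L) {
    abort(sprintf("`%s` must have exactly 3 channels, got %d", arg, dim(image)[3]))
  }
  if (check_range && (anyNA(image) || min(image) < 0 || max(image) > 1)) {
    abort(sprintf("`%s` must have values in [0, 1]", arg))
  }
  invisible(image)
}

#' Convert an RGB image to YCbCr
#'
#' Applies the fixed affine colour transform
#' `[Y, Cb, Cr]' = [16, 128, 128]' + (1/256) A [R, G, B]'`, where `A` is the
#' standard ITU-R BT.601 conversion matrix (rows
#' `(65.738, 129.057, 25.064)`, `(-37.945, -74.494, 112.439)`,
#' `(112.439, -94.154, -18.285)`).  Both chroma rows of `A` sum to zero, so
#' achromatic pixels keep `Cb = Cr = 128`.
#'
#' By default the input is expected on the unit scale (`[0, 1]` per channel)
#' and the matrix is applied to those unit values as printed; set
#' `rgb_scale = "8bit"` to apply the transform to `255 * RGB`, the
#' convention under which this matrix yields full-range digital YCbCr.
#'
#' @param image numeric array `H x W x 3` with values in `[0, 1]` (R, G, B).
#' @param rgb_scale `"unit"` (default) applies the matrix to the `[0, 1]`
#'   values; `"8bit"` multiplies by 255 first.
#' @return numeric array `H x W x 3` holding the Y, Cb and Cr planes.
#' @examples
#' img <- array(runif(12), dim = c(2, 2, 3))
#' ycc <- rgb_to_ycbcr(img)
#' @export
rgb_to_ycbcr <- function(image, rgb_scale = c("unit", "8bit")) {
  rgb_scale <- match.arg(rgb_scale)
  assert_image(image)
  d <- dim(image)
  rgb <- matrix(image, ncol = 3L)            # pixels x (R,G,B)
  if (rgb_scale == "8bit") rgb <- rgb * 255
  ycc <- rgb %*% t(.ycbcr_matrix)
  ycc <- sweep(ycc, 2L, .ycbcr_offset, "+")
  array(ycc, dim = d)
}

#' Geometric patch augmentation
#'
#' Reindexes the pixel grid of an image: `horizontal_flip` reverses the
#' x (column) index, `vertical_flip` reverses the y (row) index and
#' `rotate_180` reverses both (it equals the two flips composed).  All three
#' are involutions, commute pairwise and together with the identity form a
#' group of order four.
#'
#' @param image numeric array `H x W x C` (any channel values; both RGB and
#'   YCbCr images are accepted).
#' @param kind one of `"horizontal_flip"`, `"vertical_flip"`, `"rotate_180"`.
#' @return an array of the same dimensions with the grid reindexed.
#' @export
apply_augmentation <- function(image, kind) {
  kind <- match.arg(kind, .augmentation_kinds)
  if (!is.array(image) || length(dim(image)) != 3L) {
    abort("`image` must be a height x width x channel array")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(kind,
    horizontal_flip = image[, w:1, , drop = FALSE],
    vertical_flip   = image[h:1, , , drop = FALSE],
    rotate_180      = image[h:1, w:1, , drop = FALSE]
  )
}

#' Read an RGB image from PNG or TIFF
#'
#' 8-bit (or 16-bit) integer samples are rescaled to `[0, 1]`; grayscale
#' images are replicated to 3 channels and an alpha channel, if present, is
#' dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  img
}

#' Write an image as 8-bit PNG
#'
#' Values are clamped to `[0, 1]` and quantised to 8 bits; an image already
#' on the 8-bit lattice (multiples of 1/255) round-trips losslessly.
#'
#' @param image numeric array `H x W x 3`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  assert_image(image, check_range = FALSE)
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG path; any nonzero pixel is foreground.
#' @return logical matrix `H x W`.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a binary mask as PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
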