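# 8-bit RGB raster handling. The package's working unit is a plain numeric
# array of dimension c(height, width, 3), sRGB-encoded, each channel in
# [0, 255]. Row 1 is the top of the image; column 1 the left edge.

#' Validate and coerce an 8-bit RGB image array
#'
#' The pipeline's working unit is a numeric array of dimension
#' `c(height, width, 3)` holding sRGB-encoded channel values in `[0, 255]`
#' (row 1 = top of image). `as_image_rgb()` checks those invariants and
#' returns the array unchanged (storage mode numeric).
#'
#' @param x A numeric array of dimension `c(height, width, 3)`.
#' @return The validated array.
#' @examples
#' img <- as_image_rgb(array(128, dim = c(4, 6, 3)))
#' dim(img)
#' @export
as_image_rgb <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("an RGB image must be a 3-dimensional array (height x width x 3)")
  if (dim(x)[3] != 3L)
    stop("an RGB image must have exactly 3 channels, got ", dim(x)[3])
  if (!is.numeric(x))
    stop("image pixel values must be numeric")
  rng <- range(x)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("image channel values must lie in [0, 255]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  storage.mode(x) <- "double"
  x
}

#' Create a uniform RGB image
#'
#' @param height,width Image dimensions in pixels.
#' @param colour RGB triple in `[0, 255]` used to fill the image
#'   (default white).
#' @return An RGB image array (see [as_image_rgb()]).
#' @examples
#' blank_image(10, 20)[1, 1, ]
#' @export
blank_image <- function(height, width, colour = c(255, 255, 255)) {
  stopifnot(height >= 1, width >= 1, length(colour) == 3)
  img <- array(0, dim = c(height, width, 3))
  for (k in 1:3) img[, , k] <- colour[k]
  as_image_rgb(img)
}

#' Read an 8-bit RGB image from PNG or JPEG
#'
#' Greyscale images are expanded to three identical channels; any alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An RGB image array in `[0, 255]` (see [as_image_rgb()]).
#' @seealso [write_image_rgb()]
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)          # width x height (x channels)
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  nch <- dim(dat)[3]
  if (nch == 1L) dat <- dat[, , c(1, 1, 1), drop = FALSE]
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]   # drop alpha
  out <- aperm(dat, c(2, 1, 3)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  as_image_rgb(round_half_up(out))
}

#' Write an 8-bit RGB image to PNG or JPEG
#'
#' The format is chosen from the file extension. JPEG is written at
#' quality 100 to keep colour measurements as faithful as the format
#' allows; PNG is lossless and preferred for intermediate files.
#'
#' @param image RGB image array.
#' @param path Output path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(image, path) {
  image <- as_image_rgb(image)
  dat <- aperm(image / 255, c(2, 1, 3))
  ebi <- EBImage::Image(dat, colormode = "Color")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg"))
    stop("unsupported image format: .", ext, " (use .png, .jpg or .jpeg)")
  EBImage::writeImage(ebi, path, quality = 100L)
  invisible(path)
}

# round half away from zero at .5 (values here are non-negative, so this is
# round-half-up); base round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)

# clip to [0,255] and round half-up: the canonical re-quantisation applied
# after every arithmetic image operation
clip_quantise <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round_half_up(x)
}

# internal: image array -> EBImage grayscale Image of a logical/numeric mask
.mask_to_ebi <- function(mask) EBImage::Image(t(mask * 1))

# internal: EBImage grayscale Image -> matrix in image (row = y) convention
.ebi_to_mat <- function(img) t(EBImage::imageData(img))
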