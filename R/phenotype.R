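# Size calibration, per-object measurement, and colour-space conversion.

#' Calibrate physical scale from a reference object of known size
#'
#' The photograph must contain an object of known physical size (a coin
#' works well), placed as the left-most object so it can be identified
#' after [separate_objects()]. Separate per-axis scales are kept because
#' the pixel grid need not be square on the scene.
#'
#' @param reference A `detected_object` for the known-size object.
#' @param known_width,known_height Physical size of the reference object.
#' @param unit_name Unit label recorded with the calibration (default
#'   `"mm"`).
#' @return An object of class `size_calibration`: list with `scale_x`,
#'   `scale_y` (units per pixel) and `unit_name`.
#' @examples
#' ref <- structure(list(mask = matrix(TRUE, 50, 100),
#'                       bbox = roi(0, 0, 100, 50),
#'                       label = "ref", pixel_count = 5000L),
#'                  class = "detected_object")
#' calibrate_scale(ref, 10, 10)$scale_x  # 0.1
#' @export
calibrate_scale <- function(reference, known_width, known_height,
                            unit_name = "mm") {
  stopifnot(inherits(reference, "detected_object"))
  if (known_width <= 0 || known_height <= 0)
    stop("known reference dimensions must be positive")
  px_w <- reference$bbox$width
  px_h <- reference$bbox$height
  if (px_w < 1 || px_h < 1)
    stop("degenerate reference object: zero pixel extent")
  structure(list(scale_x = known_width / px_w,
                 scale_y = known_height / px_h,
                 unit_name = unit_name),
            class = "size_calibration")
}

#' Measure an object's physical size and mean colour
#'
#' Width and height are the axis-aligned extents of the object mask scaled
#' by the calibration; area is the mask pixel count times the pixel area.
#' The mean colour over object pixels only (background excluded) is
#' reported in sRGB, YUV (BT.601 full range) and CIELAB (D65, 2 degree
#' observer).
#'
#' @param obj A `detected_object` from [separate_objects()].
#' @param cal A [calibrate_scale()] result.
#' @param image Optional RGB image the object was detected in; when given,
#'   mean colours are computed, otherwise the colour fields are `NA`.
#' @return An object of class `object_measurement`: list with `label`,
#'   `width`, `height`, `area`, `unit_name`, `mean_rgb`, `mean_yuv`,
#'   `mean_lab`.
#' @export
measure_object <- function(obj, cal, image = NULL) {
  stopifnot(inherits(obj, "detected_object"),
            inherits(cal, "size_calibration"))
  if (obj$pixel_count < 1L) stop("degenerate object: empty mask")
  out <- list(label = obj$label,
              width = obj$bbox$width * cal$scale_x,
              height = obj$bbox$height * cal$scale_y,
              area = obj$pixel_count * cal$scale_x * cal$scale_y,
              unit_name = cal$unit_name,
              mean_rgb = rep(NA_real_, 3),
              mean_yuv = rep(NA_real_, 3),
              mean_lab = rep(NA_real_, 3))
  if (!is.null(image)) {
    rgb <- mean_object_colour(image, obj)
    out$mean_rgb <- rgb
    out$mean_yuv <- rgb_to_yuv(rgb)
    out$mean_lab <- rgb_to_lab(rgb)
  }
  structure(out, class = "object_measurement")
}

#' Mean colour of an object's pixels
#'
#' Arithmetic mean of each sRGB channel over the object mask only;
#' surrounding background pixels never enter the average.
#'
#' @param image RGB image array.
#' @param obj A `detected_object` whose bounding box lies within `image`.
#' @return RGB triple (numeric, unquantised).
#' @export
mean_object_colour <- function(image, obj) {
  image <- as_image_rgb(image)
  stopifnot(inherits(obj, "detected_object"))
  if (obj$pixel_count < 1L || !any(obj$mask))
    stop("degenerate object: empty mask")
  sub <- crop_roi(image, obj$bbox)
  v <- vapply(1:3, function(k) mean(sub[, , k][obj$mask]), numeric(1))
  names(v) <- c("R", "G", "B")
  v
}

#' Convert sRGB to YUV (BT.601 full range)
#'
#' Luma plus two chroma channels with the +128 chroma offset, so an
#' achromatic input maps to `U = V = 128` and white to `(255, 128, 128)`.
#'
#' @param rgb RGB triple, or n x 3 matrix, in `[0, 255]`.
#' @return YUV triple (or n x 3 matrix), unquantised.
#' @examples
#' rgb_to_yuv(c(255, 255, 255))  # 255 128 128
#' @export
rgb_to_yuv <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(as.numeric(rgb), 1)
  stopifnot(ncol(m) == 3)
  if (any(m < 0 | m > 255)) stop("RGB values must lie in [0, 255]")
  A <- matrix(c( 0.299,     0.587,     0.114,
                -0.168736, -0.331264,  0.5,
                 0.5,      -0.418688, -0.081312),
              nrow = 3, byrow = TRUE)
  out <- m %*% t(A)
  out[, 2] <- out[, 2] + 128
  out[, 3] <- out[, 3] + 128
  colnames(out) <- c("Y", "U", "V")
  if (is.matrix(rgb)) out else { v <- out[1, ]; names(v) <- c("Y", "U", "V"); v }
}

#' Convert sRGB to CIELAB (D65, 2 degree observer)
#'
#' The standard path: sRGB gamma decode (piecewise linear/power-2.4), the
#' sRGB-to-XYZ matrix for the D65 white point, then the CIELAB forward
#' function (cube root with the linear toe). In-gamut inputs give
#' `L*` in `[0, 100]`; `a*` and `b*` are signed.
#'
#' @param rgb RGB triple, or n x 3 matrix, in `[0, 255]`.
#' @return Lab triple (or n x 3 matrix).
#' @examples
#' rgb_to_lab(c(255, 255, 255))  # ~ (100, 0, 0)
#' @export
rgb_to_lab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(as.numeric(rgb), 1)
  stopifnot(ncol(m) == 3)
  if (any(m < 0 | m > 255)) stop("RGB values must lie in [0, 255]")
  s <- m / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1.0, 1.08883)   # D65, 2 degree observer
  t3 <- sweep(xyz, 2, wp, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (is.matrix(rgb)) out else { v <- out[1, ]; names(v) <- c("L", "a", "b"); v }
}

#' Write object measurements to CSV
#'
#' One row per object with columns
#' `object,width,height,area,R,G,B,Y,U,V,L,a,b`; numeric values are
#' written at 3 decimal places. A sidecar JSON file (same path with
#' `.json` appended) records the unit name.
#'
#' @param measurements List of [measure_object()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(measurements, path) {
  rows <- lapply(measurements, function(m) {
    stopifnot(inherits(m, "object_measurement"))
    data.frame(object = m$label,
               width = round(m$width, 3), height = round(m$height, 3),
               area = round(m$area, 3),
               R = round(m$mean_rgb[1], 3), G = round(m$mean_rgb[2], 3),
               B = round(m$mean_rgb[3], 3),
               Y = round(m$mean_yuv[1], 3), U = round(m$mean_yuv[2], 3),
               V = round(m$mean_yuv[3], 3),
               L = round(m$mean_lab[1], 3), a = round(m$mean_lab[2], 3),
               b = round(m$mean_lab[3], 3))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(), width = numeric(), height = numeric(),
               area = numeric(), R = numeric(), G = numeric(), B = numeric(),
               Y = numeric(), U = numeric(), V = numeric(), L = numeric(),
               a = numeric(), b = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  unit <- if (length(measurements)) measurements[[1]]$unit_name else "mm"
  jsonlite::write_json(list(unit_name = unit,
                            colour_spaces = c("sRGB", "YUV-BT601-full",
                                              "CIELAB-D65-2deg")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
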