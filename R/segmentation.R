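# White-background removal and object separation.

#' Define a rectangular region of interest
#'
#' Coordinates are 0-based from the top-left corner, with width/height
#' semantics (the region covers columns `x0 .. x0+width-1`).
#'
#' @param x0,y0 Top-left pixel (0-based, inclusive).
#' @param width,height Region extent in pixels (>= 1).
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, width, height) {
  stopifnot(x0 >= 0, y0 >= 0, width >= 1, height >= 1)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' Crop an image to a region of interest
#'
#' Replaces the interactive click-and-drag selection of a windowed workflow
#' with explicit coordinates, so crops are scriptable and reproducible.
#'
#' @param image RGB image array.
#' @param region An [roi()].
#' @return The `region$width` x `region$height` sub-image.
#' @examples
#' img <- blank_image(100, 100)
#' dim(crop_roi(img, roi(10, 10, 20, 10)))  # 10 20 3
#' @export
crop_roi <- function(image, region) {
  image <- as_image_rgb(image)
  stopifnot(inherits(region, "roi"))
  h <- dim(image)[1]; w <- dim(image)[2]
  x1 <- region$x0 + region$width   # exclusive
  y1 <- region$y0 + region$height
  if (x1 > w || y1 > h)
    stop("ROI (x0=", region$x0, ", y0=", region$y0, ", w=", region$width,
         ", h=", region$height, ") exceeds image bounds ", w, "x", h)
  image[(region$y0 + 1):y1, (region$x0 + 1):x1, , drop = FALSE]
}

#' Remove a white background by colour thresholding
#'
#' A pixel is classed as background when all three channels are at or
#' above `threshold` (near-white). The foreground mask is cleaned by
#' morphological opening then closing with a 5 x 5 elliptical structuring
#' element, connected components smaller than `min_object_area` pixels are
#' discarded, and background pixels are written as pure white
#' `(255, 255, 255)`.
#'
#' @param image RGB image array on a white background.
#' @param threshold Background threshold in `[0, 255]`; 150 is a good
#'   starting value — lower it if the background survives, raise it if
#'   objects are eaten into.
#' @param min_object_area Smallest connected foreground component kept,
#'   in pixels.
#' @return List with `image` (background forced to white) and `mask`
#'   (logical foreground matrix).
#' @export
remove_background <- function(image, threshold = 150, min_object_area = 500) {
  image <- as_image_rgb(image)
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single value in [0, 255]")
  fg <- !(image[, , 1] >= threshold &
          image[, , 2] >= threshold &
          image[, , 3] >= threshold)
  fg <- clean_mask(fg, min_object_area)
  out <- image
  for (k in 1:3) {
    ch <- out[, , k]
    ch[!fg] <- 255
    out[, , k] <- ch
  }
  list(image = as_image_rgb(out), mask = fg)
}

# opening then closing with an elliptical (disc) 5x5 element, then drop
# components below min_object_area
clean_mask <- function(mask, min_object_area) {
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(5L, shape = "disc")
  m <- .mask_to_ebi(mask)
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  lab <- .ebi_to_mat(EBImage::bwlabel(m))
  if (min_object_area > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_area)
    lab[!(lab %in% keep)] <- 0
  }
  lab > 0
}

#' Separate the objects of a background-removed image
#'
#' Labels the connected components of the non-white pixel mask, drops
#' components below `min_object_area`, and returns one detected object per
#' component, sorted left to right by bounding-box x (ties broken by y).
#' Touching or overlapping objects form a single merged component — a
#' documented limitation; keep objects separated at capture time.
#'
#' @param image RGB image array whose background is (near-)white, e.g. the
#'   output of [remove_background()].
#' @param labels Optional character vector of object names assigned in
#'   sorted order; defaults to `obj_001`, `obj_002`, ...
#' @param min_object_area Smallest component returned, in pixels.
#' @param white_threshold Channel floor at or above which (all three
#'   channels) a pixel counts as background. Default 250.
#' @return List of `detected_object`s, each with `mask` (logical matrix),
#'   `bbox` (an [roi()], the tight bounding box), `label` and
#'   `pixel_count`. Zero objects is a valid result (empty list).
#' @export
separate_objects <- function(image, labels = NULL, min_object_area = 500,
                             white_threshold = 250) {
  image <- as_image_rgb(image)
  fg <- !(image[, , 1] >= white_threshold &
          image[, , 2] >= white_threshold &
          image[, , 3] >= white_threshold)
  if (!any(fg)) return(list())
  lab <- .ebi_to_mat(EBImage::bwlabel(.mask_to_ebi(fg)))
  n <- max(lab)
  objs <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_object_area) next
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    mask <- lab[y0:y1, x0:x1, drop = FALSE] == i
    objs[[length(objs) + 1L]] <- structure(
      list(mask = mask,
           bbox = roi(x0 - 1L, y0 - 1L, x1 - x0 + 1L, y1 - y0 + 1L),
           label = NA_character_,
           pixel_count = nrow(idx)),
      class = "detected_object")
  }
  if (!length(objs)) return(list())
  ord <- order(vapply(objs, function(o) o$bbox$x0, integer(1)),
               vapply(objs, function(o) o$bbox$y0, integer(1)))
  objs <- objs[ord]
  for (i in seq_along(objs)) {
    objs[[i]]$label <- if (!is.null(labels) && i <= length(labels))
      labels[i] else sprintf("obj_%03d", i)
  }
  objs
}

#' Extract one object as its own white-background image
#'
#' @param image The RGB image the object was detected in.
#' @param obj A `detected_object` from [separate_objects()].
#' @return RGB image array of the object's bounding box with all
#'   non-object pixels set to white.
#' @export
object_image <- function(image, obj) {
  image <- as_image_rgb(image)
  stopifnot(inherits(obj, "detected_object"))
  sub <- crop_roi(image, obj$bbox)
  for (k in 1:3) {
    ch <- sub[, , k]
    ch[!obj$mask] <- 255
    sub[, , k] <- ch
  }
  sub
}

#' @export
print.detected_object <- function(x, ...) {
  cat("Detected object", x$label, "-", x$pixel_count, "px, bbox",
      x$bbox$width, "x", x$bbox$height, "at (", x$bbox$x0, ",",
      x$bbox$y0, ")\n")
  invisible(x)
}
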