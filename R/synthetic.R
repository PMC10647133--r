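# Deterministic synthetic scenes: a checker card plus objects on a white
# background, with ground-truth manifests, parametric camera distortion
# (vignette, channelwise cast, noise), and simulated calibration datasets.
# Rendering is hard-edged (no anti-aliasing) so pixel counts are exact.

#' Specify a synthetic checker-plus-objects scene
#'
#' The default scene emulates the recommended capture layout: a portrait
#' 4 x 6 checker card on the left of a white background, a grey square
#' reference object of known physical size as the left-most non-checker
#' object, and disc-shaped "plant" objects to its right.
#'
#' @param width,height Image size in pixels.
#' @param checker List `x0, y0, width, height, border` (pixels; 0-based
#'   corner) plus `orientation` (`"portrait"` or `"landscape-cw"`);
#'   `border` is the dark frame thickness and `border_colour` its RGB.
#' @param swatches A [swatch_set()] of the 24 rendered swatch colours.
#' @param reference_object List `x0, y0, width, height, colour,
#'   known_width, known_height, unit` for the known-size object.
#' @param objects List of object specs: `shape = "disc"` with `cx, cy,
#'   radius` or `shape = "rect"` with `x0, y0, width, height`; each with
#'   `colour` (RGB) and optional `label`.
#' @param allow_overlap Skip the non-overlap validation (for rendering
#'   deliberately touching objects).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 640, height = 480,
                       checker = list(x0 = 40, y0 = 60, width = 200,
                                      height = 290, border = 10,
                                      border_colour = c(15, 15, 15),
                                      orientation = "portrait"),
                       swatches = synthetic_reference_swatches(),
                       reference_object = list(x0 = 280, y0 = 220,
                                               width = 40, height = 40,
                                               colour = c(128, 128, 128),
                                               known_width = 10,
                                               known_height = 10,
                                               unit = "mm"),
                       objects = list(
                         list(shape = "disc", cx = 400, cy = 140,
                              radius = 35, colour = c(200, 80, 50)),
                         list(shape = "disc", cx = 400, cy = 340,
                              radius = 30, colour = c(190, 160, 60)),
                         list(shape = "disc", cx = 530, cy = 240,
                              radius = 40, colour = c(120, 170, 80))),
                       allow_overlap = FALSE) {
  spec <- structure(list(width = as.integer(width),
                         height = as.integer(height),
                         checker = checker, swatches = swatches,
                         reference_object = reference_object,
                         objects = objects,
                         allow_overlap = isTRUE(allow_overlap)),
                    class = "scene_spec")
  boxes <- .scene_boxes(spec)
  for (b in boxes)
    if (b[1] < 0 || b[2] < 0 || b[3] > width || b[4] > height)
      stop("scene geometry out of image bounds")
  if (!spec$allow_overlap && length(boxes) > 1) {
    for (i in seq_along(boxes)[-1]) for (j in seq_len(i - 1)) {
      a <- boxes[[i]]; b <- boxes[[j]]
      if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
        stop("scene geometry overlaps (elements ", j, " and ", i,
             "); set allow_overlap = TRUE to render touching objects")
    }
  }
  spec
}

# bounding boxes c(x0, y0, x1exclusive, y1exclusive), 0-based
.scene_boxes <- function(spec) {
  ck <- spec$checker; ro <- spec$reference_object
  boxes <- list(c(ck$x0, ck$y0, ck$x0 + ck$width, ck$y0 + ck$height))
  if (!is.null(ro))
    boxes <- c(boxes, list(c(ro$x0, ro$y0, ro$x0 + ro$width,
                             ro$y0 + ro$height)))
  for (ob in spec$objects) {
    boxes <- c(boxes, list(
      if (ob$shape == "disc")
        c(ob$cx - ob$radius, ob$cy - ob$radius,
          ob$cx + ob$radius + 1, ob$cy + ob$radius + 1)
      else c(ob$x0, ob$y0, ob$x0 + ob$width, ob$y0 + ob$height)))
  }
  boxes
}

#' Render a synthetic scene with its ground truth
#'
#' Renders the scene hard-edged on a white background: the checker as a
#' dark-bordered 4 x 6 card with the anchor swatch in the convention
#' corner, then the reference object and plant objects. Rendering is
#' deterministic; the returned truth manifest is consistent with the
#' image by construction.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (RGB array) and `truth`: list with
#'   `swatch_rgb` (24 x 3, convention order), `objects` (data frame:
#'   label, shape, pixel_count, bbox coordinates, true colour, physical
#'   width/height/area under the declared reference scale), `reference`
#'   (pixel extent, known size, implied scales) and `checker_rect`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  img <- blank_image(spec$height, spec$width)
  ck <- spec$checker
  sw <- as.matrix(spec$swatches)

  # card frame
  img <- .fill_rect(img, ck$x0, ck$y0, ck$width, ck$height, ck$border_colour)
  gx0 <- ck$x0 + ck$border; gy0 <- ck$y0 + ck$border
  gw <- ck$width - 2 * ck$border; gh <- ck$height - 2 * ck$border
  portrait <- !identical(ck$orientation, "landscape-cw")
  ncol_grid <- if (portrait) 4L else 6L
  nrow_grid <- if (portrait) 6L else 4L
  xb <- round(seq(gx0, gx0 + gw, length.out = ncol_grid + 1))
  yb <- round(seq(gy0, gy0 + gh, length.out = nrow_grid + 1))
  for (r in seq_len(nrow_grid)) for (cc in seq_len(ncol_grid)) {
    # convention swatch index for this grid cell
    if (portrait) { pr <- r; pc <- cc } else { pr <- 7L - cc; pc <- r }
    idx <- (pc - 1L) * 6L + pr
    img <- .fill_rect(img, xb[cc], yb[r], xb[cc + 1] - xb[cc],
                      yb[r + 1] - yb[r], sw[idx, ])
  }

  ro <- spec$reference_object
  ref_truth <- NULL
  if (!is.null(ro)) {
    img <- .fill_rect(img, ro$x0, ro$y0, ro$width, ro$height, ro$colour)
    ref_truth <- list(pixel_width = ro$width, pixel_height = ro$height,
                      known_width = ro$known_width,
                      known_height = ro$known_height, unit = ro$unit,
                      scale_x = ro$known_width / ro$width,
                      scale_y = ro$known_height / ro$height)
  }

  rows <- list()
  for (i in seq_along(spec$objects)) {
    ob <- spec$objects[[i]]
    lab <- if (!is.null(ob$label)) ob$label else sprintf("obj_%03d", i)
    if (ob$shape == "disc") {
      res <- .fill_disc(img, ob$cx, ob$cy, ob$radius, ob$colour)
      img <- res$image; npix <- res$count; bb <- res$bbox
    } else {
      img <- .fill_rect(img, ob$x0, ob$y0, ob$width, ob$height, ob$colour)
      npix <- ob$width * ob$height
      bb <- c(ob$x0, ob$y0, ob$width, ob$height)
    }
    sx <- if (is.null(ref_truth)) NA_real_ else ref_truth$scale_x
    sy <- if (is.null(ref_truth)) NA_real_ else ref_truth$scale_y
    rows[[i]] <- data.frame(label = lab, shape = ob$shape,
                            pixel_count = npix,
                            x0 = bb[1], y0 = bb[2],
                            bbox_width = bb[3], bbox_height = bb[4],
                            R = ob$colour[1], G = ob$colour[2],
                            B = ob$colour[3],
                            phys_width = bb[3] * sx, phys_height = bb[4] * sy,
                            phys_area = npix * sx * sy)
  }
  objects <- if (length(rows)) do.call(rbind, rows) else NULL

  list(image = as_image_rgb(img),
       truth = list(swatch_rgb = sw, objects = objects,
                    reference = ref_truth,
                    checker_rect = c(x0 = ck$x0, y0 = ck$y0,
                                     width = ck$width, height = ck$height),
                    orientation = ck$orientation))
}

.fill_rect <- function(img, x0, y0, w, h, colour) {
  ys <- (y0 + 1):(y0 + h); xs <- (x0 + 1):(x0 + w)
  for (k in 1:3) img[ys, xs, k] <- colour[k]
  img
}

.fill_disc <- function(img, cx, cy, radius, colour) {
  ys <- pmax(1, cy - radius + 1):(cy + radius + 1)
  xs <- pmax(1, cx - radius + 1):(cx + radius + 1)
  yy <- outer(ys - 1, rep(1, length(xs)))
  xx <- outer(rep(1, length(ys)), xs - 1)
  inside <- (xx - cx)^2 + (yy - cy)^2 <= radius^2
  for (k in 1:3) {
    sub <- img[ys, xs, k]
    sub[inside] <- colour[k]
    img[ys, xs, k] <- sub
  }
  idx <- which(inside, arr.ind = TRUE)
  bx0 <- min(xs[idx[, 2]]) - 1; by0 <- min(ys[idx[, 1]]) - 1
  bw <- max(xs[idx[, 2]]) - 1 - bx0 + 1
  bh <- max(ys[idx[, 1]]) - 1 - by0 + 1
  list(image = img, count = sum(inside), bbox = c(bx0, by0, bw, bh))
}

#' Render the matching flat-field (background) exposure of a scene
#'
#' The empty white scene at the spec's dimensions — what the camera sees
#' for the background shot. Distort it with the same
#' [apply_camera_distortion()] parameters as the scene to emulate a
#' background capture under identical conditions.
#'
#' @param spec A [scene_spec()].
#' @return A white RGB image of the scene's dimensions.
#' @export
render_background <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  blank_image(spec$height, spec$width)
}

#' Apply a parametric camera distortion to an image
#'
#' Emulates capture imperfections in a fixed order: a radial vignette
#' (multiplicative; 1 at the image centre falling to `1 - strength` at the
#' farthest corner), then a channelwise cubic colour cast applied on the
#' unit scale (`c' = a1 c + a2 c^2 + a3 c^3`, no constant term — the same
#' model class the colour correction fits), then additive Gaussian noise,
#' then clipping to `[0, 255]` and re-quantisation.
#'
#' @param image RGB image array.
#' @param cast List with components `R`, `G`, `B`, each `c(a1, a2, a3)`
#'   on the unit scale; `NULL` for the identity cast.
#' @param vignette_strength In `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation in 8-bit units
#'   (>= 0).
#' @param seed Integer seed for the noise (mandatory whenever
#'   `noise_sd > 0`; the global RNG state is preserved).
#' @return The distorted RGB image array.
#' @export
apply_camera_distortion <- function(image, cast = NULL,
                                    vignette_strength = 0, noise_sd = 0,
                                    seed = 1) {
  image <- as_image_rgb(image)
  stopifnot(vignette_strength >= 0, vignette_strength < 1, noise_sd >= 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  if (vignette_strength > 0) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d2 <- outer(((1:h) - cy)^2, rep(1, w)) +
      outer(rep(1, h), ((1:w) - cx)^2)
    field <- 1 - vignette_strength * d2 / max(d2)
    for (k in 1:3) out[, , k] <- out[, , k] * field
  }
  if (!is.null(cast)) {
    for (k in 1:3) {
      a <- cast[[c("R", "G", "B")[k]]]
      stopifnot(length(a) == 3)
      u <- out[, , k] / 255
      out[, , k] <- 255 * (a[1] * u + a[2] * u^2 + a[3] * u^3)
    }
  }
  if (noise_sd > 0)
    out <- out + .with_seed(seed, array(stats::rnorm(length(out),
                                                     sd = noise_sd),
                                        dim = dim(out)))
  as_image_rgb(clip_quantise(out))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a pigment calibration dataset from a model
#'
#' Draws predictors uniformly over `x_range` and generates responses from
#' the model plus additive Gaussian noise — the generator behind the
#' parameter-recovery tests. With `noise_sd = 0` every row satisfies the
#' model equation exactly.
#'
#' @param model A `pigment_model` (fitted, constructed with
#'   [lycopene_model()] / [chlorophyll_model()], or loaded from JSON).
#' @param n Number of rows (>= 1).
#' @param x_range For a lycopene model, `c(min, max)` of the `a*/b*`
#'   ratio; for a chlorophyll model, a 2 x 3 matrix of per-channel RGB
#'   ranges. Defaults to the model's training range.
#' @param noise_sd Response noise SD (>= 0).
#' @param seed Integer seed (mandatory; the global RNG state is
#'   preserved).
#' @return A data frame in the training-CSV dialect
#'   (`id,a_over_b,lycopene` or `id,R,G,B,chlorophyll`).
#' @export
simulate_pigment_dataset <- function(model, n, x_range = NULL,
                                     noise_sd = 0, seed = 1) {
  stopifnot(inherits(model, "pigment_model"), n >= 1)
  .with_seed(seed, {
    if (inherits(model, "lycopene_model")) {
      if (is.null(x_range)) x_range <- model$training_range
      x <- stats::runif(n, x_range[1], x_range[2])
      y <- as.numeric(predict(model, x)) + stats::rnorm(n, sd = noise_sd)
      data.frame(id = seq_len(n), a_over_b = x, lycopene = y)
    } else {
      if (is.null(x_range)) x_range <- model$training_range
      rgb <- cbind(stats::runif(n, x_range[1, 1], x_range[2, 1]),
                   stats::runif(n, x_range[1, 2], x_range[2, 2]),
                   stats::runif(n, x_range[1, 3], x_range[2, 3]))
      ct <- as.numeric(predict(model, rgb)) + stats::rnorm(n, sd = noise_sd)
      data.frame(id = seq_len(n), R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                 chlorophyll = ct)
    }
  })
}

#' Write / read a scene spec as JSON
#'
#' @param spec A [scene_spec()].
#' @param path JSON path.
#' @return `path` (write) or a `scene_spec` (read).
#' @export
write_scene_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  obj <- unclass(spec)
  obj$swatches <- as.data.frame(as.matrix(spec$swatches))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_spec_json
#' @export
read_scene_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$objects <- lapply(seq_len(nrow(obj$objects)), function(i) {
    o <- as.list(obj$objects[i, ])
    o$colour <- unlist(o$colour)
    o
  })
  obj$checker$border_colour <- unlist(obj$checker$border_colour)
  obj$reference_object$colour <- unlist(obj$reference_object$colour)
  scene_spec(width = obj$width, height = obj$height,
             checker = as.list(obj$checker),
             swatches = swatch_set(obj$swatches),
             reference_object = as.list(obj$reference_object),
             objects = obj$objects,
             allow_overlap = obj$allow_overlap)
}
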