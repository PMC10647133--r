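# Flat-field background correction, checker swatch sampling, and
# per-channel third-order polynomial colour correction.

#' Flat-field (background) correction
#'
#' Corrects an experimental image for vignetting and lighting
#' non-uniformity using a photograph of the empty, evenly lit scene taken
#' under the same camera settings. The background image is blurred with a
#' 5 x 5 arithmetic-mean kernel, normalised per channel to `[0, 1]` by
#' dividing by that channel's maximum, and the experimental image is
#' divided elementwise by the normalised field. The result is clipped to
#' `[0, 255]` and re-quantised to integers.
#'
#' Normalised background values of 0 are floored at 1/255 before the
#' division so a dead pixel cannot produce an infinite quotient.
#'
#' @param image Experimental RGB image array.
#' @param background Background RGB image of identical dimensions.
#' @return The corrected RGB image array.
#' @examples
#' img <- blank_image(16, 16, c(200, 200, 200))
#' identical(background_correct(img, img), img)
#' @export
background_correct <- function(image, background) {
  image <- as_image_rgb(image)
  background <- as_image_rgb(background)
  if (!identical(dim(image), dim(background)))
    stop("image and background dimensions differ: ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(background)[1:2], collapse = "x"))
  blurred <- box_blur(background, size = 5L)
  out <- image
  for (k in 1:3) {
    mx <- max(blurred[, , k])
    if (mx == 0)
      stop("degenerate background: channel ", c("R", "G", "B")[k],
           " is zero everywhere")
    field <- blurred[, , k] / mx
    field[field < 1 / 255] <- 1 / 255
    out[, , k] <- image[, , k] / field
  }
  as_image_rgb(clip_quantise(out))
}

# 5x5 (or any odd size) arithmetic-mean blur with replicated edges,
# applied per channel
box_blur <- function(image, size = 5L) {
  stopifnot(size %% 2L == 1L)
  kern <- matrix(1 / size^2, size, size)
  out <- image
  for (k in 1:3) {
    ch <- EBImage::Image(t(image[, , k]))
    out[, , k] <- .ebi_to_mat(EBImage::filter2(ch, kern, boundary = "replicate"))
  }
  out
}

#' Euclidean colour error between two RGB triples
#'
#' The per-swatch colour error: the Euclidean distance between an observed
#' and a reference colour in 8-bit RGB space. Zero iff the triples are
#' equal; at most `255 * sqrt(3)` (about 441.67).
#'
#' @param observed,reference RGB triples in `[0, 255]`.
#' @return Non-negative scalar distance.
#' @examples
#' delta_rgb(c(3, 0, 4), c(0, 0, 0))  # 5
#' @export
delta_rgb <- function(observed, reference) {
  stopifnot(length(observed) == 3, length(reference) == 3)
  if (any(observed < 0 | observed > 255 | reference < 0 | reference > 255))
    stop("RGB triples must lie in [0, 255]")
  sqrt(sum((as.numeric(observed) - as.numeric(reference))^2))
}

#' Mean swatch colour error of a sampled checker
#'
#' Arithmetic mean of the 24 per-swatch Euclidean errors ([delta_rgb()])
#' between the observed swatch means and the reference values — the
#' whole-image colour-accuracy score reported before and after colour
#' correction.
#'
#' @param observed A [sample_checker()] result (`swatch_grid`) or 24 x 3
#'   matrix of observed swatch means.
#' @param reference A [swatch_set()] or 24 x 3 matrix of reference values.
#' @return Mean error (RGB units).
#' @export
mean_swatch_error <- function(observed, reference) {
  obs <- observed_matrix(observed)
  ref <- as.matrix(reference)
  stopifnot(nrow(obs) == 24L, nrow(ref) == 24L)
  mean(sqrt(rowSums((obs - ref)^2)))
}

observed_matrix <- function(x) {
  if (inherits(x, "swatch_grid")) x$observed_rgb else as.matrix(x)
}

#' Locate and sample the 24 swatches of a colour checker
#'
#' Finds the checker card as the largest near-rectangular dark-bordered
#' connected region (or uses the supplied corner hint), splits the card
#' interior into a 4 x 6 grid, samples the mean RGB of the central 50% of
#' each cell, and resolves the card's orientation by matching the anchor
#' (light-blue) swatch so the result follows the package ordering
#' convention (see [load_reference_swatches()]).
#'
#' The card must be axis-aligned (portrait or landscape). Rotated cards
#' are not detected: crop and rotate the photograph so the checker is
#' square to the image, or pass `hint`.
#'
#' @param image RGB image array containing the checker.
#' @param hint Optional `c(x0, y0, x1, y1)` (0-based, inclusive) corners of
#'   the swatch-grid area, bypassing detection.
#' @param reference Optional [swatch_set()]; when given, orientation is
#'   resolved by total colour distance over all 24 swatches instead of the
#'   anchor swatch alone.
#' @param anchor_rgb Reference colour of the anchor swatch used for
#'   orientation (default: the bundled light-blue anchor).
#' @param dark_threshold Channel ceiling (all three channels) below which a
#'   pixel counts as card border. Default 60.
#' @return An object of class `swatch_grid`: list with `observed_rgb`
#'   (24 x 3 matrix in convention order), `cell_polygons` (list of 4 x 2
#'   corner matrices, x then y, 0-based), and `orientation` (one of
#'   `"portrait"`, `"portrait-180"`, `"landscape-cw"`, `"landscape-ccw"`).
#' @export
sample_checker <- function(image, hint = NULL, reference = NULL,
                           anchor_rgb = .default_anchor_rgb(),
                           dark_threshold = 60) {
  image <- as_image_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]

  if (is.null(hint)) {
    grid_rect <- detect_checker_card(image, dark_threshold)
  } else {
    stopifnot(length(hint) == 4)
    grid_rect <- list(x0 = hint[1] + 1, y0 = hint[2] + 1,
                      x1 = hint[3] + 1, y1 = hint[4] + 1)
    if (grid_rect$x0 < 1 || grid_rect$y0 < 1 || grid_rect$x1 > w ||
        grid_rect$y1 > h || grid_rect$x1 <= grid_rect$x0 ||
        grid_rect$y1 <= grid_rect$y0)
      stop("checker hint rectangle is invalid or outside image bounds")
  }

  gw <- grid_rect$x1 - grid_rect$x0 + 1
  gh <- grid_rect$y1 - grid_rect$y0 + 1
  portrait <- gh >= gw
  ncol_grid <- if (portrait) 4L else 6L
  nrow_grid <- if (portrait) 6L else 4L

  xb <- round(seq(grid_rect$x0, grid_rect$x1 + 1, length.out = ncol_grid + 1))
  yb <- round(seq(grid_rect$y0, grid_rect$y1 + 1, length.out = nrow_grid + 1))

  cell_mean <- matrix(NA_real_, nrow_grid * ncol_grid, 3)
  cell_poly <- vector("list", nrow_grid * ncol_grid)
  for (r in seq_len(nrow_grid)) {
    for (cc in seq_len(ncol_grid)) {
      idx <- (r - 1L) * ncol_grid + cc
      x0 <- xb[cc]; x1 <- xb[cc + 1] - 1
      y0 <- yb[r];  y1 <- yb[r + 1] - 1
      # central 50% of the cell, away from cell borders
      cx0 <- x0 + floor((x1 - x0 + 1) * 0.25)
      cx1 <- x1 - floor((x1 - x0 + 1) * 0.25)
      cy0 <- y0 + floor((y1 - y0 + 1) * 0.25)
      cy1 <- y1 - floor((y1 - y0 + 1) * 0.25)
      cell_mean[idx, ] <- vapply(1:3, function(k)
        mean(image[cy0:cy1, cx0:cx1, k]), numeric(1))
      cell_poly[[idx]] <- cbind(x = c(x0, x1, x1, x0) - 1,
                                y = c(y0, y0, y1, y1) - 1)
    }
  }

  ords <- .orientation_orders(portrait, nrow_grid, ncol_grid)
  score <- vapply(ords, function(o) {
    m <- cell_mean[o$index, , drop = FALSE]
    if (!is.null(reference))
      sum(sqrt(rowSums((m - as.matrix(reference))^2)))
    else
      sqrt(sum((m[ANCHOR_INDEX, ] - anchor_rgb)^2))
  }, numeric(1))
  best <- ords[[which.min(score)]]

  structure(list(observed_rgb = {
                   m <- cell_mean[best$index, , drop = FALSE]
                   colnames(m) <- c("R", "G", "B"); m
                 },
                 cell_polygons = cell_poly[best$index],
                 orientation = best$name),
            class = "swatch_grid")
}

# Candidate mappings from convention index (column-major portrait, anchor
# top right) to row-major cell index of the sampled grid. For each of the
# 24 convention positions (r = 1..6 down, c = 1..4 right) compute where
# that swatch sits in the image grid under each admissible rotation.
.orientation_orders <- function(portrait, nrow_grid, ncol_grid) {
  conv <- expand.grid(r = 1:6, c = 1:4)   # convention order: columns major
  rowmajor <- function(r, c) (r - 1L) * ncol_grid + c
  if (portrait) {
    list(
      list(name = "portrait",
           index = rowmajor(conv$r, conv$c)),
      list(name = "portrait-180",
           index = rowmajor(7L - conv$r, 5L - conv$c))
    )
  } else {
    list(
      # card rotated 90 deg clockwise into landscape:
      # portrait (r, c) -> image (row = c, col = 7 - r)
      list(name = "landscape-cw",
           index = rowmajor(conv$c, 7L - conv$r)),
      # rotated 90 deg counter-clockwise:
      list(name = "landscape-ccw",
           index = rowmajor(5L - conv$c, conv$r))
    )
  }
}

# Detect the card: largest connected component of dark pixels whose
# bounding box is traced by the component (a rectangular border ring) and
# whose aspect ratio is near 4:6. Returns the swatch-grid rectangle (the
# border ring's interior), 1-based inclusive.
detect_checker_card <- function(image, dark_threshold) {
  dark <- image[, , 1] < dark_threshold &
          image[, , 2] < dark_threshold &
          image[, , 3] < dark_threshold
  if (!any(dark))
    stop("no colour checker card found: no dark card border detected; ",
         "crop/rotate the image so the checker is square, or pass a hint")
  lab <- .ebi_to_mat(EBImage::bwlabel(.mask_to_ebi(dark)))
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  ys <- which(lab == comp, arr.ind = TRUE)
  y0 <- min(ys[, 1]); y1 <- max(ys[, 1])
  x0 <- min(ys[, 2]); x1 <- max(ys[, 2])
  bw <- x1 - x0 + 1; bh <- y1 - y0 + 1

  aspect <- max(bw, bh) / min(bw, bh)
  if (aspect < 1.2 || aspect > 1.8)
    stop("checker detection failed: candidate card aspect ratio ",
         signif(aspect, 3), " outside the 4:6 tolerance; ",
         "crop/rotate the image so the checker is square, or pass a hint")

  # a straight border ring traces its own bounding box: require most of the
  # bounding-box perimeter to be dark (fails for rotated cards)
  per <- c(lab[y0, x0:x1], lab[y1, x0:x1], lab[y0:y1, x0], lab[y0:y1, x1])
  if (mean(per == comp) < 0.9)
    stop("checker detection failed: card border is not axis-aligned; ",
         "crop/rotate the image so the checker is square, or pass a hint")

  # border thickness: shortest dark run walking inward along the midlines
  mid_y <- (y0 + y1) %/% 2; mid_x <- (x0 + x1) %/% 2
  run <- function(v) { n <- 0L; for (p in v) { if (p) n <- n + 1L else break }; n }
  t_left   <- run(lab[mid_y, x0:x1] == comp)
  t_right  <- run(lab[mid_y, x1:x0] == comp)
  t_top    <- run(lab[y0:y1, mid_x] == comp)
  t_bottom <- run(lab[y1:y0, mid_x] == comp)
  bt <- min(t_left, t_right, t_top, t_bottom, floor(min(bw, bh) * 0.2))
  bt <- max(bt, 1L)
  list(x0 = x0 + bt, y0 = y0 + bt, x1 = x1 - bt, y1 = y1 - bt)
}

#' Fit the per-channel polynomial colour correction
#'
#' For each of the R, G and B channels an ordinary-least-squares regression
#' maps the observed swatch colours to the reference values through a
#' nine-term third-order basis with no intercept:
#' \deqn{CC = \beta_1 R + \beta_2 G + \beta_3 B + \beta_4 R^2 + \beta_5 G^2
#'   + \beta_6 B^2 + \beta_7 R^3 + \beta_8 G^3 + \beta_9 B^3}
#' Channels are scaled to `[0, 1]` (division by 255) before the quadratic
#' and cubic terms are formed, which conditions the design matrix; the
#' coefficients are stored on that unit scale. A per-channel r-squared
#' (`1 - SSR/SST`, SST about the reference-channel mean) is recorded; all
#' three should exceed 0.95 for a successfully correctable image.
#'
#' @param observed A `swatch_grid` from [sample_checker()] (or 24 x 3
#'   matrix of observed swatch means), ordered as the reference.
#' @param reference A [swatch_set()] (or 24 x 3 matrix).
#' @return An object of class `colour_correction`: list with
#'   `coefficients` (9 x 3 matrix, one column per output channel),
#'   `input_scale = "unit"` and `r2` (named length-3 vector).
#' @seealso [apply_colour_correction()]
#' @export
fit_colour_correction <- function(observed, reference) {
  obs <- observed_matrix(observed)
  ref <- as.matrix(reference)
  stopifnot(nrow(obs) == 24L, ncol(obs) == 3L,
            nrow(ref) == 24L, ncol(ref) == 3L)
  X <- poly_basis(obs / 255)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("colour correction is not identifiable: the swatch design matrix ",
         "is rank deficient (rank ", qrX$rank, " of 9); the observed ",
         "swatches do not span the polynomial basis")
  Yref <- ref / 255
  beta <- qr.coef(qrX, Yref)
  fitted <- X %*% beta
  r2 <- vapply(1:3, function(k) {
    ssr <- sum((Yref[, k] - fitted[, k])^2)
    sst <- sum((Yref[, k] - mean(Yref[, k]))^2)
    1 - ssr / sst
  }, numeric(1))
  names(r2) <- c("R", "G", "B")
  rownames(beta) <- c("R", "G", "B", "R2", "G2", "B2", "R3", "G3", "B3")
  colnames(beta) <- c("R", "G", "B")
  structure(list(coefficients = beta, input_scale = "unit", r2 = r2),
            class = "colour_correction")
}

# nine-term cubic basis on unit-scaled channels; m is n x 3 in [0,1]
poly_basis <- function(m) {
  cbind(m[, 1], m[, 2], m[, 3],
        m[, 1]^2, m[, 2]^2, m[, 3]^2,
        m[, 1]^3, m[, 2]^3, m[, 3]^3)
}

#' Apply a fitted colour correction to an image
#'
#' Transforms every pixel through the nine-term polynomial of the fitted
#' [fit_colour_correction()] model (on the model's unit input scale), then
#' clips to `[0, 255]` and re-quantises.
#'
#' @param image RGB image array.
#' @param model A `colour_correction` model.
#' @return The corrected RGB image array.
#' @export
apply_colour_correction <- function(image, model) {
  image <- as_image_rgb(image)
  stopifnot(inherits(model, "colour_correction"))
  beta <- model$coefficients
  stopifnot(length(beta) == 27L)
  d <- dim(image)
  m <- matrix(image, ncol = 3) / 255     # pixels x 3
  out <- poly_basis(m) %*% beta * 255
  as_image_rgb(clip_quantise(array(out, dim = d)))
}

#' Correct RGB triples through a fitted colour correction
#'
#' Convenience wrapper applying the polynomial of a `colour_correction`
#' model to a matrix of RGB triples (e.g. swatch means) instead of a full
#' image. Values are clipped to `[0, 255]` but not re-quantised.
#'
#' @param rgb n x 3 matrix of RGB values in `[0, 255]`.
#' @param model A `colour_correction` model.
#' @return n x 3 matrix of corrected values.
#' @export
correct_rgb <- function(rgb, model) {
  stopifnot(inherits(model, "colour_correction"))
  m <- as.matrix(rgb)
  out <- poly_basis(m / 255) %*% model$coefficients * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  colnames(out) <- c("R", "G", "B")
  out
}

#' @export
print.colour_correction <- function(x, ...) {
  cat("Polynomial colour correction (9-term cubic, no intercept,",
      "unit input scale)\n")
  cat("Per-channel r-squared:",
      paste(sprintf("%s = %.4f", names(x$r2), x$r2), collapse = ", "), "\n")
  if (any(x$r2 < 0.95))
    cat("Warning: r-squared below 0.95; the image may not be",
        "successfully correctable\n")
  invisible(x)
}

#' Check a corrected white swatch for channel saturation
#'
#' Colour correction that drives the white swatch to the 255 ceiling in any
#' channel indicates clipped highlights; the corrected white swatch value
#' is logged so this can be monitored across a batch.
#'
#' @param corrected_white_swatch RGB triple of the corrected white swatch.
#' @return List with `saturated` (TRUE if any channel equals 255) and
#'   `rgb` (the triple, for logging).
#' @examples
#' check_white_saturation(c(250, 250, 250))$saturated  # FALSE
#' check_white_saturation(c(255, 250, 248))$saturated  # TRUE
#' @export
check_white_saturation <- function(corrected_white_swatch) {
  v <- as.numeric(corrected_white_swatch)
  stopifnot(length(v) == 3)
  if (any(v < 0 | v > 255)) stop("white swatch triple must lie in [0, 255]")
  list(saturated = any(v == 255), rgb = v)
}
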