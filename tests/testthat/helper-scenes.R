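# Shared fixtures: all images are generated in code at test time.

# a moderate channelwise cubic cast within the correction model class
# (unit-scale, no constant term)
moderate_cast <- function() {
  list(R = c(0.92, 0.10, -0.05),
       G = c(0.85, 0.12, 0.00),
       B = c(0.95, -0.08, 0.05))
}

# render the default scene, distort it and its background exposure with
# the same camera parameters, and flat-field correct; returns the image
# ready for colour correction plus the scene truth
distorted_scene <- function(seed, cast = moderate_cast(),
                            vignette = 0.2, noise_sd = 2,
                            spec = scene_spec()) {
  scene <- render_scene(spec)
  img <- apply_camera_distortion(scene$image, cast, vignette, noise_sd,
                                 seed = seed)
  bg <- apply_camera_distortion(render_background(spec), cast, vignette,
                                noise_sd, seed = seed + 1000L)
  list(corrected_bg = background_correct(img, bg),
       distorted = img, truth = scene$truth, spec = spec)
}

# plain white image with hard-edged discs drawn on it (no checker)
disc_image <- function(height, width, discs) {
  img <- blank_image(height, width)
  for (d in discs) {
    ys <- (d$cy - d$r):(d$cy + d$r) + 1
    xs <- (d$cx - d$r):(d$cx + d$r) + 1
    yy <- outer(ys - 1, rep(1, length(xs)))
    xx <- outer(rep(1, length(ys)), xs - 1)
    inside <- (xx - d$cx)^2 + (yy - d$cy)^2 <= d$r^2
    for (k in 1:3) {
      sub <- img[ys, xs, k]
      sub[inside] <- d$colour[k]
      img[ys, xs, k] <- sub
    }
  }
  img
}

# exact rasterised pixel count of a disc as drawn by disc_image()
disc_pixel_count <- function(r) {
  xx <- outer(-r:r, rep(1, 2 * r + 1))
  yy <- t(xx)
  sum(xx^2 + yy^2 <= r^2)
}

# a detected_object built directly from a logical mask placed at (x0, y0)
manual_object <- function(mask, x0 = 0, y0 = 0, label = "obj") {
  structure(list(mask = mask,
                 bbox = roi(x0, y0, ncol(mask), nrow(mask)),
                 label = label, pixel_count = sum(mask)),
            class = "detected_object")
}
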