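test_that("reference swatch CSVs are validated on load", {
  ref <- synthetic_reference_swatches()
  expect_s3_class(ref, "swatch_set")
  expect_equal(nrow(ref), 24L)
  expect_equal(attr(ref, "order_convention"),
               "column-major-portrait-anchor-top-right")

  short <- tempfile(fileext = ".csv")
  write.csv(data.frame(R = 1:23, G = 1:23, B = 1:23), short,
            row.names = FALSE)
  expect_error(load_reference_swatches(short), "23 rows")

  bad <- tempfile(fileext = ".csv")
  df <- as.data.frame(as.matrix(ref))
  df$R[7] <- 300
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_reference_swatches(bad), "row 7")
})

test_that("swatch CSV writing round-trips through the loader", {
  ref <- synthetic_reference_swatches()
  path <- tempfile(fileext = ".csv")
  write_swatch_csv(ref, path)
  again <- load_reference_swatches(path)
  expect_equal(as.matrix(again), as.matrix(ref))
})

test_that("flat-field correction is the identity for a uniform pair and clips", {
  img <- blank_image(16, 16, c(200, 200, 200))
  expect_identical(background_correct(img, img), img)

  # quotient above 255 is stored as 255
  dark_bg <- blank_image(16, 16, c(100, 100, 100))
  out <- background_correct(img, dark_bg)   # uniform field: divides by 1
  expect_true(all(out <= 255))
  half_bg <- blank_image(16, 16, c(200, 200, 200))
  half_bg[, 1:8, ] <- 100                  # field 0.5 on the left half
  out <- background_correct(img, half_bg)
  expect_true(all(out[, 1:4, ] == 255))    # 200 / 0.5 clipped

  expect_error(background_correct(img, blank_image(8, 8)), "dimensions")
  expect_error(background_correct(img, blank_image(16, 16, c(0, 0, 0))),
               "degenerate background")
})

test_that("flat-field correction flattens a vignetted field", {
  flat <- blank_image(120, 160, c(180, 170, 160))
  vign <- apply_camera_distortion(flat, vignette_strength = 0.3)
  bg <- apply_camera_distortion(blank_image(120, 160),
                                vignette_strength = 0.3)
  out <- background_correct(vign, bg)
  for (k in 1:3) {
    cv <- sd(out[, , k]) / mean(out[, , k])
    expect_lt(cv, 0.01)
  }
})

test_that("flat-field correction is idempotent under a uniform background", {
  img <- blank_image(20, 20, c(130, 140, 150))
  img[5:10, 5:10, ] <- 60
  bg <- blank_image(20, 20, c(210, 210, 210))
  once <- background_correct(img, bg)
  expect_identical(background_correct(once, bg), once)
})

test_that("checker sampling recovers rendered swatches in all orientations", {
  ref <- synthetic_reference_swatches()
  scene <- render_scene(scene_spec())
  g <- sample_checker(scene$image)
  expect_equal(g$orientation, "portrait")
  expect_equal(length(g$cell_polygons), 24L)
  expect_lt(max(abs(g$observed_rgb - as.matrix(ref))), 2)

  rot <- scene$image[dim(scene$image)[1]:1, dim(scene$image)[2]:1, ,
                     drop = FALSE]
  g180 <- sample_checker(rot)
  expect_equal(g180$orientation, "portrait-180")
  expect_lt(max(abs(g180$observed_rgb - as.matrix(ref))), 2)

  land <- scene_spec(
    checker = list(x0 = 40, y0 = 60, width = 290, height = 200,
                   border = 10, border_colour = c(15, 15, 15),
                   orientation = "landscape-cw"),
    reference_object = list(x0 = 360, y0 = 300, width = 40, height = 40,
                            colour = c(128, 128, 128), known_width = 10,
                            known_height = 10, unit = "mm"),
    objects = list(list(shape = "disc", cx = 450, cy = 120, radius = 30,
                        colour = c(200, 80, 50))))
  gl <- sample_checker(render_scene(land)$image)
  expect_equal(gl$orientation, "landscape-cw")
  expect_lt(max(abs(gl$observed_rgb - as.matrix(ref))), 2)
})

test_that("checker detection fails informatively without an upright card", {
  expect_error(sample_checker(blank_image(100, 100)), "no dark card")

  # filled dark square: aspect ratio far from 4:6
  sq <- blank_image(200, 200)
  sq[51:150, 51:150, ] <- 20
  expect_error(sample_checker(sq), "aspect")

  # card rotated 30 degrees: bounding box no longer traced by the border
  rot <- blank_image(400, 400)
  th <- 30 * pi / 180
  for (y in 1:400) for (x in 1:400) {
    u <- cos(th) * (x - 200) + sin(th) * (y - 200)
    v <- -sin(th) * (x - 200) + cos(th) * (y - 200)
    if (abs(u) < 60 && abs(v) < 95 && (abs(u) > 50 || abs(v) > 85))
      rot[y, x, ] <- 20
  }
  expect_error(sample_checker(rot), "crop/rotate")
})

test_that("checker hint bypasses detection", {
  scene <- render_scene(scene_spec())   # grid region: (50,70)-(229,339)
  g <- sample_checker(scene$image, hint = c(50, 70, 229, 339))
  expect_lt(max(abs(g$observed_rgb -
                      as.matrix(synthetic_reference_swatches()))), 2)
  expect_error(sample_checker(scene$image, hint = c(500, 70, 700, 339)),
               "hint")
})

test_that("colour-correction fit is exact on identity and linear maps", {
  ref <- as.matrix(synthetic_reference_swatches())

  m_id <- fit_colour_correction(ref, ref)
  expect_equal(unname(m_id$r2), rep(1, 3), tolerance = 1e-9)
  expect_lt(max(abs(correct_rgb(ref, m_id) - ref)), 1)

  halved <- ref / 2
  m_half <- fit_colour_correction(halved, ref)
  expect_lt(max(abs(correct_rgb(halved, m_half) - ref)), 1)

  expect_error(
    fit_colour_correction(matrix(100, 24, 3), ref), "rank deficient")
})

test_that("fitting inverts a known channelwise cubic cast", {
  ref <- as.matrix(synthetic_reference_swatches())
  cast <- moderate_cast()
  u <- ref / 255
  observed <- sapply(1:3, function(k) {
    a <- cast[[k]]
    255 * (a[1] * u[, k] + a[2] * u[, k]^2 + a[3] * u[, k]^3)
  })
  model <- fit_colour_correction(observed, ref)
  expect_true(all(model$r2 > 0.95))
  expect_lt(max(abs(correct_rgb(observed, model) - ref)), 1)
})

test_that("applying a correction transforms whole images as specified", {
  img <- blank_image(10, 10, c(60, 120, 240))
  beta <- matrix(0, 9, 3)
  beta[1, 1] <- 1; beta[2, 2] <- 1; beta[3, 3] <- 1   # identity model
  ident <- structure(list(coefficients = beta, input_scale = "unit",
                          r2 = c(R = 1, G = 1, B = 1)),
                     class = "colour_correction")
  expect_identical(apply_colour_correction(img, ident), img)

  zero <- ident; zero$coefficients <- matrix(0, 9, 3)
  expect_true(all(apply_colour_correction(img, zero) == 0))

  ref <- as.matrix(synthetic_reference_swatches())
  m_half <- fit_colour_correction(ref / 2, ref)
  half_img <- blank_image(8, 8, ref[9, ] / 2)
  out <- apply_colour_correction(half_img, m_half)
  expect_lt(max(abs(out[4, 4, ] - ref[9, ])), 1)
})

test_that("the swatch error is a metric with the documented values", {
  expect_equal(delta_rgb(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(delta_rgb(c(3, 0, 4), c(0, 0, 0)), 5)
  expect_equal(delta_rgb(c(255, 255, 255), c(0, 0, 0)), 441.673,
               tolerance = 1e-6)

  set.seed(11)
  for (i in 1:200) {
    a <- runif(3, 0, 255); b <- runif(3, 0, 255); c <- runif(3, 0, 255)
    expect_gte(delta_rgb(a, b), 0)
    expect_equal(delta_rgb(a, b), delta_rgb(b, a))
    expect_lte(delta_rgb(a, c), delta_rgb(a, b) + delta_rgb(b, c) + 1e-12)
  }
  expect_equal(delta_rgb(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("mean swatch error averages the 24 per-swatch errors", {
  ref <- as.matrix(synthetic_reference_swatches())
  expect_equal(mean_swatch_error(ref, ref), 0)
  # all errors equal to 10: displace each swatch by 10 along one in-range axis
  disp <- ref
  for (i in 1:24) {
    k <- which(ref[i, ] + 10 <= 255)[1]
    if (is.na(k)) { k <- which(ref[i, ] - 10 >= 0)[1]; disp[i, k] <- ref[i, k] - 10 }
    else disp[i, k] <- ref[i, k] + 10
  }
  expect_equal(mean_swatch_error(disp, ref), 10)
})

test_that("white-swatch saturation is flagged at the channel ceiling", {
  expect_true(check_white_saturation(c(255, 250, 248))$saturated)
  expect_true(check_white_saturation(c(255, 255, 255))$saturated)
  expect_false(check_white_saturation(c(250, 250, 250))$saturated)
  expect_equal(check_white_saturation(c(1, 2, 3))$rgb, c(1, 2, 3))
})

test_that("correction of distorted synthetic scenes reduces swatch error", {
  ref <- synthetic_reference_swatches()
  for (seed in c(3, 17)) {
    ds <- distorted_scene(seed)
    before <- sample_checker(ds$corrected_bg, reference = ref)
    model <- fit_colour_correction(before, ref)
    expect_true(all(model$r2 > 0.95))
    after <- sample_checker(apply_colour_correction(ds$corrected_bg, model),
                            reference = ref)
    e_before <- mean_swatch_error(before, ref)
    e_after <- mean_swatch_error(after, ref)
    expect_lt(e_after, e_before)
    # outputs stay valid 8-bit images
    expect_no_error(as_image_rgb(apply_colour_correction(ds$distorted, model)))
  }
})
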