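test_that("the lycopene coefficient reconstructs from physical constants", {
  k <- pigment_constants()
  coefficient <- k$lycopene_molar_mass / k$lycopene_molar_extinction *
    k$l_per_ml * k$mg_per_g * k$hexane_volume_ml * k$g_per_kg
  expect_equal(signif(coefficient, 3), 31.2)
  expect_equal(lycopene_from_absorbance(1.0, 1.0), 31.2, tolerance = 1e-3)
  expect_equal(lycopene_from_absorbance(0, 2), 0)
  expect_equal(lycopene_from_absorbance(0.5, 0.5), 31.2, tolerance = 1e-3)
  expect_error(lycopene_from_absorbance(1, 0), "positive")
  expect_error(lycopene_from_absorbance(-0.1, 1), "non-negative")
})

test_that("chlorophyll formulas are additive and match the constants", {
  expect_equal(unname(chlorophyll_from_absorbance(0, 1.0)["Ca"]), 12.21)
  expect_equal(unname(chlorophyll_from_absorbance(0, 0)), c(0, 0, 0))
  ct <- chlorophyll_from_absorbance(1.0, 1.0)
  expect_equal(unname(ct["Ct"]), (12.21 - 5.03) + (20.13 - 2.81))
  expect_equal(unname(ct["Ct"]), 24.50)
  # additivity holds everywhere
  set.seed(4)
  for (i in 1:20) {
    v <- chlorophyll_from_absorbance(runif(1, 0, 2), runif(1, 0, 2))
    expect_equal(unname(v["Ct"]), unname(v["Ca"] + v["Cb"]))
  }
  expect_error(chlorophyll_from_absorbance(-1, 0), "non-negative")
})

test_that("the exponential lycopene fit recovers noiseless parameters", {
  beta <- c(5, 2, 10)
  x <- seq(-0.5, 1.2, length.out = 20)
  y <- beta[1] * exp(beta[2] * x) + beta[3]
  fit <- fit_lycopene_model(x, y)
  expect_lt(max(abs(coef(fit) - beta) / beta), 0.001)
  expect_gt(fit$r2, 0.999999)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$training_range, range(x))
})

test_that("lycopene fit degenerate inputs raise informative errors", {
  x <- seq(0, 1, length.out = 10)
  expect_error(fit_lycopene_model(x[1:3], (1:3) * 1.0), "at least 4")
  expect_error(fit_lycopene_model(x, rep(7, 10)), "non-identifiable")
  expect_error(fit_lycopene_model(c(0, Inf, 1, 2), c(1, 2, 3, 4)),
               "non-finite")
})

test_that("lycopene parameter recovery is unbiased under noise", {
  beta <- c(5, 2, 10)
  n <- 20; reps <- 200
  y_range <- diff(range(beta[1] * exp(beta[2] * c(-0.5, 1.2)) + beta[3]))
  noise_sd <- 0.05 * y_range
  # evenly spaced calibration design spanning the a*/b* training range
  x <- seq(-0.5, 1.2, length.out = n)
  set.seed(99)
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    y <- beta[1] * exp(beta[2] * x) + beta[3] + rnorm(n, sd = noise_sd)
    est[r, ] <- tryCatch(coef(fit_lycopene_model(x, y)),
                         error = function(e) rep(NA_real_, 3))
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  expect_gt(nrow(est), 0.9 * reps)
  bias <- abs(colMeans(est) - beta) / beta
  expect_true(all(bias < 0.05))
})

test_that("lycopene predictions evaluate the curve and flag extrapolation", {
  x <- seq(-0.5, 1.2, length.out = 10)
  fit <- fit_lycopene_model(x, 2 * exp(1 * x) + 3)
  p0 <- predict(fit, 0)
  expect_equal(as.numeric(p0), 5, tolerance = 1e-6)
  expect_false(attr(p0, "extrapolated"))
  p_out <- predict(fit, 2.0)
  expect_true(attr(p_out, "extrapolated"))
  # beta2 > 0 implies the prediction increases in a*/b*
  xs <- seq(-0.5, 1.2, length.out = 50)
  expect_true(all(diff(as.numeric(predict(fit, xs))) > 0))
})

test_that("the chlorophyll log-linear fit is exact on noiseless data", {
  beta <- c(-0.01, 0.02, -0.005, 0.5)
  set.seed(7)
  rgb <- cbind(runif(12, 40, 220), runif(12, 40, 220), runif(12, 40, 220))
  ct <- exp(rgb %*% beta[1:3] + beta[4])[, 1]
  fit <- fit_chlorophyll_model(rgb, ct)
  expect_lt(max(abs(coef(fit) - beta)), 1e-10)
  expect_gt(fit$r2, 1 - 1e-10)

  expect_error(fit_chlorophyll_model(rgb, c(ct[-1], 0)), "positive")
  rgb_const <- rgb; rgb_const[, 1] <- 100
  expect_error(fit_chlorophyll_model(rgb_const, ct), "collinear")
  expect_error(fit_chlorophyll_model(rgb[1:4, ], ct[1:4]), "at least 5")
})

test_that("chlorophyll predictions exponentiate the linear form", {
  set.seed(13)
  rgb <- cbind(runif(8, 40, 220), runif(8, 40, 220), runif(8, 40, 220))
  mk <- function(beta) {
    ct <- exp(rgb %*% beta[1:3] + beta[4])[, 1]
    fit_chlorophyll_model(rgb, ct)
  }
  fit <- mk(c(0.01, 0, 0, 0))
  p <- predict(fit, c(100, 100, 100))   # inside all per-channel ranges
  expect_equal(as.numeric(p), exp(1), tolerance = 1e-8)
  expect_false(attr(p, "extrapolated"))
  p_out <- predict(fit, c(250, 100, 100))
  expect_true(attr(p_out, "extrapolated"))
})

test_that("validation statistics match hand-computed values", {
  v <- validate_model(c(1, 2, 3), c(1, 2, 3))
  expect_equal(v$r2, 1)
  expect_equal(v$rmse, 0)

  v2 <- validate_model(c(2, 3, 4), c(1, 2, 3))
  expect_equal(v2$rmse, 1)

  v3 <- validate_model(c(1.1, 1.9, 3.2, 3.8), c(1, 2, 3, 4))
  expect_equal(v3$rmse, sqrt(mean(c(0.1, 0.1, 0.2, 0.2)^2)),
               tolerance = 1e-12)
  expect_equal(mean(v3$standardised_residuals), 0, tolerance = 1e-9)
  expect_equal(v3$anova_df, c(1, 2))

  expect_error(validate_model(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(validate_model(1:4, 1:3), "equal length")
})

test_that("training-fit diagnostics agree with the validation report", {
  set.seed(21)
  x <- runif(15, -0.4, 1.1)
  y <- 4 * exp(1.8 * x) + 8 + rnorm(15, sd = 1)
  fit <- fit_lycopene_model(x, y)
  rep <- validate_model(as.numeric(predict(fit, x)), y)
  expect_equal(rep$r2, fit$r2, tolerance = 1e-12)
  expect_equal(rep$rmse, fit$rmse, tolerance = 1e-12)

  rgb <- cbind(runif(10, 40, 220), runif(10, 40, 220), runif(10, 40, 220))
  ct <- exp(-0.008 * rgb[, 1] + 0.015 * rgb[, 2] - 0.003 * rgb[, 3] + 0.4) *
    exp(rnorm(10, sd = 0.05))
  cfit <- fit_chlorophyll_model(rgb, ct)
  crep <- validate_model(as.numeric(predict(cfit)), ct)
  expect_equal(crep$r2, cfit$r2, tolerance = 1e-12)
})

test_that("pigment models round-trip through JSON serialisation", {
  x <- seq(-0.5, 1.2, length.out = 12)
  fit <- fit_lycopene_model(x, 5 * exp(2 * x) + 10)
  path <- tempfile(fileext = ".json")
  write_pigment_model_json(fit, path)
  back <- read_pigment_model_json(path)
  expect_s3_class(back, "lycopene_model")
  expect_equal(unname(coef(back)), unname(coef(fit)), tolerance = 1e-12)
  expect_equal(as.numeric(predict(back, 0.5)),
               as.numeric(predict(fit, 0.5)), tolerance = 1e-9)

  rgb <- cbind(runif(8, 40, 220), runif(8, 40, 220), runif(8, 40, 220))
  cfit <- fit_chlorophyll_model(rgb, exp(0.002 * rowSums(rgb) + 0.1))
  write_pigment_model_json(cfit, path)
  cback <- read_pigment_model_json(path)
  expect_s3_class(cback, "chlorophyll_model")
  expect_equal(unname(coef(cback)), unname(coef(cfit)), tolerance = 1e-12)
})

test_that("model objects expose the standard accessor methods", {
  x <- seq(-0.5, 1.2, length.out = 12)
  y <- 5 * exp(2 * x) + 10 + c(0.1, -0.1)
  fit <- fit_lycopene_model(x, y)
  expect_length(coef(fit), 3)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-9)
  expect_output(print(fit), "lycopene")
  sim <- simulate(fit, nsim = 6, seed = 3)
  expect_equal(nrow(sim), 6L)
})
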