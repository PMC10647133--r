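# Spectrophotometric ground-truth formulas and exponential colour-to-pigment
# calibration models (fit / predict / validate).

#' Physical constants of the lycopene extraction formula
#'
#' @return Named list: `lycopene_molar_extinction` (M^-1 cm^-1, in hexane),
#'   `lycopene_molar_mass` (g/mol), `hexane_volume_ml`, and the unit
#'   conversion factors of the concentration formula.
#' @export
pigment_constants <- function() {
  list(lycopene_molar_extinction = 17.2e4,  # M^-1 cm^-1, lycopene in hexane
       lycopene_molar_mass = 536.9,         # g/mol
       hexane_volume_ml = 10,
       l_per_ml = 1e-3,
       mg_per_g = 1e3,
       g_per_kg = 1e3)
}

# The single coefficient of the lycopene formula, recomputed from the
# constants: A/epsilon [mol/l] * M [g/mol] -> g/l; * 1e-3 l/ml -> g/ml;
# * 1e3 mg/g -> mg/ml; * 10 ml hexane -> mg; per g tissue * 1e3 g/kg
# -> mg/kg. Comes to 31.2 at 3 significant figures.
lycopene_coefficient <- function() {
  k <- pigment_constants()
  k$lycopene_molar_mass / k$lycopene_molar_extinction *
    k$l_per_ml * k$mg_per_g * k$hexane_volume_ml * k$g_per_kg
}

#' Lycopene concentration from absorbance at 503 nm
#'
#' Spectrophotometric ground truth for the calibration models: the hexane
#' extract's absorbance at 503 nm is converted to lycopene content of the
#' wet tissue,
#' \deqn{L = A_{503} \times 31.2 / m_{tissue}}
#' in mg per kg wet tissue. The coefficient 31.2 is recomputed at call
#' time from the molar extinction coefficient of lycopene in hexane
#' (17.2e4 per M per cm), its molar mass (536.9 g/mol), the 10 ml hexane
#' volume and the unit conversions, and asserted to equal 31.2 at 3
#' significant figures.
#'
#' @param a503 Absorbance at 503 nm (>= 0, measured against hexane blank).
#' @param tissue_mass Mass of tissue paste in g (> 0).
#' @return Lycopene concentration, mg per kg wet tissue.
#' @examples
#' lycopene_from_absorbance(1.0, 1.0)  # 31.2
#' @export
lycopene_from_absorbance <- function(a503, tissue_mass) {
  if (any(a503 < 0)) stop("absorbance must be non-negative")
  if (any(tissue_mass <= 0)) stop("tissue mass must be positive")
  coef <- lycopene_coefficient()
  stopifnot(signif(coef, 3) == 31.2)
  a503 * coef / tissue_mass
}

#' Chlorophyll concentrations from absorbances at 646 and 663 nm
#'
#' Spectrophotometric ground truth for 80% acetone extracts:
#' \deqn{C_a = 12.21 A_{663} - 2.81 A_{646}}
#' \deqn{C_b = 20.13 A_{646} - 5.03 A_{663}}
#' \deqn{C_t = C_a + C_b}
#'
#' @param a646,a663 Absorbances (>= 0) at 646 nm and 663 nm.
#' @return Named vector `c(Ca, Cb, Ct)` in ug/ml.
#' @examples
#' chlorophyll_from_absorbance(0, 1.0)["Ca"]  # 12.21
#' @export
chlorophyll_from_absorbance <- function(a646, a663) {
  if (any(a646 < 0) || any(a663 < 0)) stop("absorbance must be non-negative")
  ca <- 12.21 * a663 - 2.81 * a646
  cb <- 20.13 * a646 - 5.03 * a663
  c(Ca = ca, Cb = cb, Ct = ca + cb)
}

#' Fit the exponential lycopene calibration model
#'
#' Fits \deqn{L = \beta_1 e^{\beta_2 a^*/b^*} + \beta_3} by
#' Levenberg-Marquardt nonlinear least squares. Starting values are
#' derived from the data: beta3 from the smallest response, beta2 and
#' beta1 from a log-linear regression of `y - beta3 + 1e-9` on `x`
#' (the small epsilon guards points lying exactly at beta3).
#'
#' @param x CIELAB `a*/b*` ratios (finite; ensure `b* != 0` upstream).
#' @param y Lycopene contents (mg per kg wet tissue), same length as `x`.
#' @param control A [minpack.lm::nls.lm.control()] list; the default uses
#'   relative tolerance 1e-10 and the solver's iteration ceiling.
#' @return An object of class `c("lycopene_model", "pigment_model")` with
#'   components `coefficients` (beta1, beta2, beta3), `r2`, `rmse`,
#'   `training_range` (range of `x`), `fitted`, `residuals`, `data`.
#' @seealso [predict.lycopene_model()], [validate_model()]
#' @export
fit_lycopene_model <- function(x, y,
                               control = minpack.lm::nls.lm.control(
                                 ftol = 1e-10, ptol = 1e-10,
                                 maxiter = 1024)) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L)
    stop("at least 4 points are required to fit the 3-parameter ",
         "exponential model, got ", length(x))
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (stats::var(y) == 0)
    stop("non-identifiable fit: constant response leaves the rate ",
         "parameter beta2 unconstrained")
  b3_0 <- min(y)
  loglin <- stats::lm(log(y - b3_0 + 1e-9) ~ x)
  b2_0 <- unname(stats::coef(loglin)[2])
  b1_0 <- exp(unname(stats::coef(loglin)[1]))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b1 * exp(b2 * x) + b3, data = dat,
                      start = list(b1 = b1_0, b2 = b2_0, b3 = b3_0),
                      control = control),
    error = function(e)
      stop("exponential fit did not converge: ", conditionMessage(e)))
  beta <- stats::coef(fit)
  names(beta) <- c("beta1", "beta2", "beta3")
  fitted <- beta[1] * exp(beta[2] * x) + beta[3]
  res <- y - fitted
  structure(list(coefficients = beta,
                 r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
                 rmse = sqrt(mean(res^2)),
                 training_range = range(x),
                 fitted = unname(fitted),
                 residuals = unname(res),
                 data = dat,
                 predictor = "a*/b*",
                 response = "lycopene (mg/kg wet tissue)"),
            class = c("lycopene_model", "pigment_model"))
}

#' Predict lycopene content from a*/b* ratios
#'
#' Evaluates \eqn{\beta_1 e^{\beta_2 x} + \beta_3}. Predictions at ratios
#' outside the model's training range are extrapolations — the model is
#' only trusted inside the range it was calibrated on — and are flagged in
#' the `"extrapolated"` attribute of the result.
#'
#' @param object A `lycopene_model`.
#' @param x `a*/b*` ratio(s) to predict at; defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predictions with logical attribute
#'   `"extrapolated"`.
#' @export
predict.lycopene_model <- function(object, x = object$data$x, ...) {
  b <- object$coefficients
  out <- unname(b[1] * exp(b[2] * x) + b[3])
  attr(out, "extrapolated") <- x < object$training_range[1] |
    x > object$training_range[2]
  out
}

#' Fit the exponential chlorophyll calibration model
#'
#' Fits \deqn{C_t = e^{\beta_1 R + \beta_2 G + \beta_3 B + \beta_4}}
#' by ordinary least squares on the log scale — the model is exactly
#' linear in `log(Ct)`, so the fit is a single `lm()` of `log(ct)` on the
#' three channels with an intercept. (This implies a multiplicative error
#' model on the original scale; diagnostics are nevertheless reported on
#' the original scale.)
#'
#' @param rgb n x 3 matrix of mean object colours in `[0, 255]`.
#' @param ct Total chlorophyll contents (> 0), length n.
#' @return An object of class `c("chlorophyll_model", "pigment_model")`
#'   with components `coefficients` (beta1..beta4), `r2`, `rmse` (both on
#'   the original scale), `training_range` (2 x 3 matrix of per-channel
#'   ranges), `fitted`, `residuals`, `data`.
#' @export
fit_chlorophyll_model <- function(rgb, ct) {
  rgb <- as.matrix(rgb)
  ct <- as.numeric(ct)
  stopifnot(ncol(rgb) == 3)
  if (nrow(rgb) != length(ct)) stop("rgb and ct must have equal length")
  if (nrow(rgb) < 5L)
    stop("at least 5 points are required to fit the 4-parameter ",
         "exponential model, got ", nrow(rgb))
  if (any(ct <= 0))
    stop("chlorophyll contents must be positive (the model is fitted on ",
         "the log scale)")
  df <- data.frame(R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                   logct = log(ct))
  fit <- stats::lm(logct ~ R + G + B, data = df)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: predictor(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " are collinear (constant channel?)")
  beta <- c(beta1 = unname(cf["R"]), beta2 = unname(cf["G"]),
            beta3 = unname(cf["B"]), beta4 = unname(cf["(Intercept)"]))
  fitted <- exp(beta[1] * rgb[, 1] + beta[2] * rgb[, 2] +
                beta[3] * rgb[, 3] + beta[4])
  res <- ct - fitted
  tr <- apply(rgb, 2, range)
  dimnames(tr) <- list(c("min", "max"), c("R", "G", "B"))
  structure(list(coefficients = beta,
                 r2 = 1 - sum(res^2) / sum((ct - mean(ct))^2),
                 rmse = sqrt(mean(res^2)),
                 training_range = tr,
                 fitted = unname(fitted),
                 residuals = unname(res),
                 data = cbind(df[, c("R", "G", "B")], ct = ct),
                 predictor = "mean RGB",
                 response = "total chlorophyll"),
            class = c("chlorophyll_model", "pigment_model"))
}

#' Predict chlorophyll content from mean RGB
#'
#' Evaluates \eqn{e^{\beta_1 R + \beta_2 G + \beta_3 B + \beta_4}}.
#' Predictions at colours with any channel outside the per-channel
#' training range are flagged as extrapolations.
#'
#' @param object A `chlorophyll_model`.
#' @param rgb RGB triple or n x 3 matrix in `[0, 255]`; defaults to the
#'   training data.
#' @param ... Unused.
#' @return Numeric vector of predictions with logical attribute
#'   `"extrapolated"`.
#' @export
predict.chlorophyll_model <- function(object,
                                      rgb = as.matrix(
                                        object$data[, c("R", "G", "B")]),
                                      ...) {
  m <- if (is.matrix(rgb)) rgb else matrix(as.numeric(rgb), ncol = 3)
  b <- object$coefficients
  out <- unname(exp(m %*% b[1:3] + b[4])[, 1])
  tr <- object$training_range
  attr(out, "extrapolated") <- vapply(seq_len(nrow(m)), function(i)
    any(m[i, ] < tr["min", ] | m[i, ] > tr["max", ]), logical(1))
  out
}

#' @export
coef.pigment_model <- function(object, ...) object$coefficients

#' @export
fitted.pigment_model <- function(object, ...) object$fitted

#' @export
residuals.pigment_model <- function(object, ...) object$residuals

#' @export
print.pigment_model <- function(x, ...) {
  kind <- if (inherits(x, "lycopene_model")) "Exponential lycopene model"
          else "Exponential chlorophyll model"
  cat(kind, "\n")
  cat("  ", if (inherits(x, "lycopene_model"))
        "L = beta1 * exp(beta2 * a*/b*) + beta3"
      else "Ct = exp(beta1*R + beta2*G + beta3*B + beta4)", "\n")
  cat("Coefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("r-squared %.4f, RMSE %.4g, n = %d\n",
              x$r2, x$rmse, nrow(x$data)))
  invisible(x)
}

#' @export
summary.pigment_model <- function(object, ...) {
  print(object)
  cat("Training range:\n")
  if (inherits(object, "lycopene_model"))
    cat("  a*/b* in [", signif(object$training_range[1], 4), ",",
        signif(object$training_range[2], 4), "]\n")
  else
    print(signif(object$training_range, 4))
  obs <- object$fitted + object$residuals
  print(validate_model(object$fitted, obs))
  invisible(object)
}

#' Plot a fitted pigment calibration model
#'
#' For the lycopene model, observed responses against the `a*/b*` ratio
#' with the fitted curve; for the chlorophyll model, predicted against
#' observed contents with the y = x line.
#'
#' @param x A `pigment_model`.
#' @param ... Passed to [plot()].
#' @export
plot.pigment_model <- function(x, ...) {
  if (inherits(x, "lycopene_model")) {
    plot(x$data$x, x$data$y, xlab = "a*/b*",
         ylab = x$response, main = "Exponential lycopene calibration", ...)
    xx <- seq(min(x$data$x), max(x$data$x), length.out = 200)
    graphics::lines(xx, predict(x, xx))
  } else {
    plot(x$data$ct, x$fitted, xlab = "observed", ylab = "predicted",
         main = "Chlorophyll calibration: predicted vs observed", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Simulate responses from a fitted pigment model
#'
#' Delegates to [simulate_pigment_dataset()]: predictors drawn uniformly
#' over the model's training range with Gaussian response noise.
#'
#' @param object A `pigment_model`.
#' @param nsim Number of points.
#' @param seed Integer seed (required for reproducibility).
#' @param noise_sd Response noise standard deviation.
#' @param ... Unused.
#' @return A data frame in the training-CSV dialect.
#' @export
simulate.pigment_model <- function(object, nsim = 20, seed = 1,
                                   noise_sd = 0, ...) {
  simulate_pigment_dataset(object, n = nsim, noise_sd = noise_sd,
                           seed = seed)
}

#' Validation statistics for predicted vs observed values
#'
#' Computes the accuracy report used to validate a calibration model on
#' held-out data: r-squared about the y = x line
#' (`1 - SS(pred - obs) / SS(obs - mean)`), the r-squared of the
#' regression of predicted on observed, RMSE of prediction, standardised
#' residuals, and the F test (with degrees of freedom and p value) of the
#' predicted-on-observed regression.
#'
#' @param predicted,observed Equal-length numeric vectors, n >= 3.
#' @return An object of class `validation_report`: list with `r2`
#'   (about y = x), `r2_regression`, `rmse`, `standardised_residuals`,
#'   `anova_F`, `anova_df` (length 2), `anova_p`, `n`.
#' @export
validate_model <- function(predicted, observed) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  n <- length(observed)
  if (n < 3L) stop("at least 3 points are required for validation")
  if (stats::var(observed) == 0)
    stop("degenerate validation set: observed values have zero variance")
  res <- observed - predicted
  r2 <- 1 - sum(res^2) / sum((observed - mean(observed))^2)
  rmse <- sqrt(mean(res^2))
  sdres <- stats::sd(res)
  std_res <- if (sdres > 0) res / sdres else res * 0
  fit <- stats::lm(predicted ~ observed)
  # perfect fits trip lm's "essentially perfect fit" warning; harmless here
  an <- suppressWarnings(stats::anova(fit))
  structure(list(r2 = r2,
                 r2_regression = suppressWarnings(summary(fit)$r.squared),
                 rmse = rmse,
                 standardised_residuals = std_res,
                 anova_F = an$`F value`[1],
                 anova_df = c(an$Df[1], an$Df[2]),
                 anova_p = an$`Pr(>F)`[1],
                 n = n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model validation (n =", x$n, ")\n")
  cat(sprintf("  r-squared (about y = x): %.4f   regression r-squared: %.4f\n",
              x$r2, x$r2_regression))
  cat(sprintf("  RMSE: %.4g\n", x$rmse))
  cat(sprintf("  ANOVA predicted ~ observed: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova_df[1], x$anova_df[2], x$anova_F, x$anova_p))
  invisible(x)
}

#' Read a pigment training CSV
#'
#' Two dialects: `id,a_over_b,lycopene` (lycopene model) or
#' `id,R,G,B,chlorophyll` (chlorophyll model).
#'
#' @param path CSV path.
#' @return A data frame; attribute `"model"` is `"lycopene"` or
#'   `"chlorophyll"`.
#' @export
read_pigment_training_csv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("a_over_b", "lycopene") %in% names(df)))
    attr(df, "model") <- "lycopene"
  else if (all(c("R", "G", "B", "chlorophyll") %in% names(df)))
    attr(df, "model") <- "chlorophyll"
  else
    stop("unrecognised training CSV: expected columns id,a_over_b,lycopene ",
         "or id,R,G,B,chlorophyll")
  df
}

#' Serialise a fitted pigment model to JSON
#'
#' @param model A `pigment_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pigment_model_json <- function(model, path) {
  stopifnot(inherits(model, "pigment_model"))
  obj <- list(formula = if (inherits(model, "lycopene_model"))
                "lycopene: b1*exp(b2*x)+b3" else
                "chlorophyll: exp(b1*R+b2*G+b3*B+b4)",
              class = class(model)[1],
              coefficients = as.list(model$coefficients),
              r2 = model$r2, rmse = model$rmse,
              training_range = if (is.matrix(model$training_range))
                as.data.frame(model$training_range) else
                model$training_range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a pigment model serialised by [write_pigment_model_json()]
#'
#' @param path JSON path.
#' @return A `pigment_model` (prediction-capable; training data absent).
#' @export
read_pigment_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$coefficients)
  if (obj$class == "lycopene_model") {
    structure(list(coefficients = beta, r2 = obj$r2, rmse = obj$rmse,
                   training_range = as.numeric(obj$training_range),
                   data = data.frame(x = as.numeric(obj$training_range),
                                     y = NA_real_),
                   predictor = "a*/b*",
                   response = "lycopene (mg/kg wet tissue)"),
              class = c("lycopene_model", "pigment_model"))
  } else {
    tr <- as.matrix(obj$training_range)
    rownames(tr) <- c("min", "max")
    structure(list(coefficients = beta, r2 = obj$r2, rmse = obj$rmse,
                   training_range = tr,
                   data = data.frame(R = tr[, 1], G = tr[, 2], B = tr[, 3],
                                     ct = NA_real_),
                   predictor = "mean RGB",
                   response = "total chlorophyll"),
              class = c("chlorophyll_model", "pigment_model"))
  }
}
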