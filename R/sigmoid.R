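#' Sigmoid heart-rate observation model
#'
#' Constructs the observation model used by the core-temperature filter: a
#' four-parameter logistic curve mapping core temperature (°C) to expected
#' heart rate (bpm),
#' \deqn{m(T_c) = d + \frac{a}{1 + \exp(-(T_c - c)/b)}}
#' with floor \eqn{d} (asymptote as \eqn{T_c \to -\infty}), amplitude \eqn{a}
#' (so the ceiling is \eqn{d + a}), midpoint \eqn{c} (temperature at half
#' amplitude) and scale \eqn{b > 0} (inverse steepness). The model also
#' carries the two noise variances the filter needs: the observation noise
#' variance (bpm²) and the process noise variance (°C² per minute).
#'
#' @param floor_hr Heart-rate floor \eqn{d} in bpm.
#' @param amplitude Heart-rate amplitude \eqn{a} in bpm; must be positive.
#' @param midpoint Temperature \eqn{c} (°C) at which HR is halfway between
#'   floor and ceiling.
#' @param scale Steepness scale \eqn{b} in °C; must be positive. The maximum
#'   slope of the curve is `amplitude / (4 * scale)` bpm/°C, attained at the
#'   midpoint.
#' @param obs_noise_var Observation (sensor + model) noise variance in bpm²;
#'   must be positive.
#' @param process_noise_var Per-minute growth of state variance in °C²;
#'   non-negative. Default 0.000484 °C²/min (about 0.022 °C/min drift),
#'   appropriate for the gradual core-temperature dynamics of continuous
#'   exercise.
#'
#' @return An object of class `hr_sigmoid`.
#' @seealso [fit_sigmoid()] to estimate the parameters from paired data,
#'   [sigmoid_hr()] for the forward curve, [estimate_tc()] for the filter.
#' @examples
#' m <- hr_sigmoid(floor_hr = 55, amplitude = 150, midpoint = 38.1,
#'                 scale = 0.55, obs_noise_var = 9)
#' sigmoid_hr(m, c(37, 38.1, 39.5))
#' @export
hr_sigmoid <- function(floor_hr, amplitude, midpoint, scale,
                       obs_noise_var, process_noise_var = 0.000484) {
  vals <- c(floor_hr = floor_hr, amplitude = amplitude, midpoint = midpoint,
            scale = scale, obs_noise_var = obs_noise_var,
            process_noise_var = process_noise_var)
  if (any(!is.finite(vals)))
    stopf("all hr_sigmoid parameters must be finite")
  if (amplitude <= 0) stopf("amplitude must be > 0")
  if (scale <= 0) stopf("scale must be > 0")
  if (obs_noise_var <= 0) stopf("obs_noise_var must be > 0")
  if (process_noise_var < 0) stopf("process_noise_var must be >= 0")
  structure(
    list(floor_hr = floor_hr, amplitude = amplitude, midpoint = midpoint,
         scale = scale, obs_noise_var = obs_noise_var,
         process_noise_var = process_noise_var),
    class = "hr_sigmoid")
}

#' Expected heart rate at a core temperature
#'
#' Evaluates the sigmoid observation curve \eqn{m(T_c)}.
#'
#' @param model An [hr_sigmoid()] model.
#' @param tc Core temperature(s) in °C.
#' @return Expected heart rate(s) in bpm.
#' @export
sigmoid_hr <- function(model, tc) {
  stopifnot(inherits(model, "hr_sigmoid"))
  model$floor_hr + model$amplitude /
    (1 + exp(-(tc - model$midpoint) / model$scale))
}

#' Slope of the observation curve
#'
#' Derivative \eqn{m'(T_c) = a\,s(1-s)/b} with \eqn{s} the logistic term;
#' this is the linearisation the extended Kalman filter uses.
#'
#' @inheritParams sigmoid_hr
#' @return Slope(s) in bpm per °C.
#' @export
sigmoid_hr_deriv <- function(model, tc) {
  stopifnot(inherits(model, "hr_sigmoid"))
  s <- 1 / (1 + exp(-(tc - model$midpoint) / model$scale))
  model$amplitude * s * (1 - s) / model$scale
}

#' Invert the observation curve
#'
#' Core temperature at which the expected heart rate equals `hr`. Defined
#' only for `hr` strictly inside the open range
#' (`floor_hr`, `floor_hr + amplitude`).
#'
#' @inheritParams sigmoid_hr
#' @param hr Heart rate(s) in bpm, strictly inside the curve's open range.
#' @return Core temperature(s) in °C.
#' @export
sigmoid_hr_inverse <- function(model, hr) {
  stopifnot(inherits(model, "hr_sigmoid"))
  u <- (hr - model$floor_hr) / model$amplitude
  if (any(u <= 0 | u >= 1))
    stopf("hr must lie strictly inside (floor_hr, floor_hr + amplitude)")
  model$midpoint + model$scale * log(u / (1 - u))
}

#' Fit the sigmoid observation model from paired data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of heart rate against core
#' temperature under the four-parameter logistic curve. The observation
#' noise variance is estimated as the residual mean square; the process
#' noise variance is not identifiable from static pairs and is passed
#' through from the argument.
#'
#' Either give a formula such as `hr ~ tc` together with `data`, or the two
#' vectors directly via `tc` and `hr`.
#'
#' @param formula Optional two-sided formula `hr ~ tc` naming columns of
#'   `data` (response = heart rate, predictor = core temperature).
#' @param data Data frame holding the columns named in `formula`.
#' @param tc,hr Numeric vectors of paired core temperature (°C) and heart
#'   rate (bpm); used when `formula` is missing.
#' @param process_noise_var Process noise variance (°C²/min) stored in the
#'   returned model; see [hr_sigmoid()].
#' @param start Optional named list of starting values
#'   (`floor_hr`, `amplitude`, `midpoint`, `scale`); self-started from the
#'   data when omitted.
#'
#' @details At least 8 pairs spanning more than 1 °C of core temperature are
#'   required; a narrower span cannot pin down the midpoint and scale.
#'
#' @return An object of class `c("hr_sigmoid_fit", "hr_sigmoid")`: a fitted
#'   [hr_sigmoid()] model with components `fit` (the underlying `nls`
#'   object), `std_errors` (named vector for the four curve parameters),
#'   `data` (the pairs used) and `n`.
#' @examples
#' truth <- hr_sigmoid(55, 150, 38.1, 0.55, obs_noise_var = 9)
#' tc <- seq(36.5, 40.3, length.out = 120)
#' hr <- sigmoid_hr(truth, tc) + rnorm(120, sd = 3)
#' f <- fit_sigmoid(tc = tc, hr = hr)
#' coef(f)
#' @export
fit_sigmoid <- function(formula = NULL, data = NULL, tc = NULL, hr = NULL,
                        process_noise_var = 0.000484, start = NULL) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    hr <- mf[[1L]]
    tc <- mf[[2L]]
  }
  if (is.null(tc) || is.null(hr))
    stopf("supply either `formula` + `data` or the `tc` and `hr` vectors")
  keep <- is.finite(tc) & is.finite(hr)
  tc <- tc[keep]; hr <- hr[keep]
  if (length(tc) < 8L)
    stopf("need at least 8 paired observations, got %d", length(tc))
  if (diff(range(tc)) <= 1)
    stopf("core temperature span must exceed 1 degree C (got %.3f)",
          diff(range(tc)))

  if (is.null(start)) {
    # self-start: anchor asymptotes just outside the observed HR range,
    # midpoint at the Tc where HR crosses its midrange
    lo <- min(hr); hi <- max(hr); rng <- hi - lo
    mid_hr <- (lo + hi) / 2
    start <- list(
      floor_hr  = lo - 0.05 * rng,
      amplitude = 1.1 * rng,
      midpoint  = stats::approx(hr, tc, xout = mid_hr, ties = mean)$y %||%
        stats::median(tc),
      scale     = diff(range(tc)) / 6
    )
    if (!is.finite(start$midpoint)) start$midpoint <- stats::median(tc)
  }

  df <- data.frame(tc = tc, hr = hr)
  fit <- minpack.lm::nlsLM(
    hr ~ floor_hr + amplitude / (1 + exp(-(tc - midpoint) / scale)),
    data = df, start = start,
    lower = c(floor_hr = -Inf, amplitude = 1e-8, midpoint = -Inf,
              scale = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  dof <- max(length(hr) - 4L, 1L)
  obs_var <- sum(res^2) / dof
  # zero-residual fits (noiseless pairs) would give a degenerate filter
  obs_var <- max(obs_var, .Machine$double.eps)

  model <- hr_sigmoid(est[["floor_hr"]], est[["amplitude"]],
                      est[["midpoint"]], est[["scale"]],
                      obs_noise_var = obs_var,
                      process_noise_var = process_noise_var)
  model$fit <- fit
  model$std_errors <- summary(fit)$coefficients[, "Std. Error"]
  model$data <- df
  model$n <- nrow(df)
  class(model) <- c("hr_sigmoid_fit", "hr_sigmoid")
  model
}

#' @export
print.hr_sigmoid <- function(x, digits = 4, ...) {
  cat("Sigmoid HR observation model: ",
      "m(Tc) = d + a / (1 + exp(-(Tc - c)/b))\n", sep = "")
  cat(sprintf("  floor d = %.*g bpm, amplitude a = %.*g bpm,\n",
              digits, x$floor_hr, digits, x$amplitude))
  cat(sprintf("  midpoint c = %.*g degC, scale b = %.*g degC\n",
              digits, x$midpoint, digits, x$scale))
  cat(sprintf("  obs noise var = %.*g bpm^2, process noise var = %.*g degC^2/min\n",
              digits, x$obs_noise_var, digits, x$process_noise_var))
  invisible(x)
}

#' @export
print.hr_sigmoid_fit <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf("  fitted to %d pairs; residual SD = %.*g bpm\n",
              x$n, digits, sqrt(x$obs_noise_var)))
  invisible(x)
}

#' @export
coef.hr_sigmoid <- function(object, ...) {
  c(floor_hr = object$floor_hr, amplitude = object$amplitude,
    midpoint = object$midpoint, scale = object$scale)
}

#' @export
summary.hr_sigmoid_fit <- function(object, ...) {
  out <- list(coefficients = cbind(Estimate = coef(object),
                                   `Std. Error` = object$std_errors),
              obs_noise_var = object$obs_noise_var,
              process_noise_var = object$process_noise_var,
              n = object$n)
  class(out) <- "summary.hr_sigmoid_fit"
  out
}

#' @export
print.summary.hr_sigmoid_fit <- function(x, ...) {
  cat("Fitted sigmoid HR observation model (", x$n, " pairs)\n", sep = "")
  print(x$coefficients)
  cat(sprintf("Observation noise variance: %.4g bpm^2\n", x$obs_noise_var))
  invisible(x)
}

#' @export
predict.hr_sigmoid <- function(object, newdata = NULL, tc = NULL, ...) {
  if (is.null(tc)) {
    if (is.data.frame(newdata) && "tc" %in% names(newdata)) tc <- newdata$tc
    else if (is.numeric(newdata)) tc <- newdata
    else if (inherits(object, "hr_sigmoid_fit")) tc <- object$data$tc
    else stopf("supply core temperatures via `tc` or `newdata`")
  }
  sigmoid_hr(object, tc)
}

#' @export
residuals.hr_sigmoid_fit <- function(object, ...) {
  object$data$hr - sigmoid_hr(object, object$data$tc)
}

#' Simulate heart rate from a core-temperature profile
#'
#' Draws minute heart rates `HR_t = m(Tc_t) + N(0, noise_sd^2)` under the
#' model's observation curve — the generator used by filter-consistency
#' checks where heart rate is produced by the very model the filter assumes.
#'
#' @param object An [hr_sigmoid()] model.
#' @param nsim Number of replicate series (columns) to draw.
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @param tc_profile Core-temperature series (°C), one value per minute.
#' @param noise_sd Observation noise SD in bpm; default
#'   `sqrt(obs_noise_var)`.
#' @param ... Unused.
#' @return For `nsim = 1` a numeric vector of bpm values the length of
#'   `tc_profile`; otherwise a matrix with `nsim` columns.
#' @export
simulate.hr_sigmoid <- function(object, nsim = 1, seed = NULL,
                                tc_profile, noise_sd = NULL, ...) {
  stopifnot(is.numeric(tc_profile), all(is.finite(tc_profile)))
  noise_sd <- noise_sd %||% sqrt(object$obs_noise_var)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  mu <- sigmoid_hr(object, tc_profile)
  draw <- function() mu + if (noise_sd > 0)
    stats::rnorm(length(mu), 0, noise_sd) else 0
  run <- function() {
    out <- replicate(nsim, draw())
    if (nsim == 1) drop(out) else out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
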