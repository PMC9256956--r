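#' One extended Kalman filter update
#'
#' Advances the scalar core-temperature filter by one minute. The time
#' update carries the mean forward unchanged (random-walk state model) and
#' inflates the variance by the process noise; the measurement update
#' linearises the sigmoid observation curve at the prior mean and applies
#' the standard Kalman gain:
#' \deqn{v^- = v + \gamma^2, \quad \hat c = m'(\hat x), \quad
#'       k = v^-\hat c / (\hat c^2 v^- + \sigma^2)}
#' \deqn{\hat x^+ = \hat x + k\,(HR - m(\hat x)), \quad
#'       v^+ = (1 - k\hat c)\,v^-}
#'
#' A missing heart rate (`NA`) applies the time update only: the prior is
#' carried forward and the variance grows.
#'
#' @param state List with elements `tc_hat` (°C) and `variance` (°C²), as
#'   returned by this function or assembled by hand.
#' @param hr Minute-average heart rate in bpm, or `NA` to skip the
#'   measurement update.
#' @param model An [hr_sigmoid()] observation model.
#' @return Updated state: a list with `tc_hat` and `variance`.
#' @examples
#' m <- hr_sigmoid(55, 150, 38.1, 0.55, obs_noise_var = 9)
#' kalman_step(list(tc_hat = 37, variance = 0.02), hr = 120, model = m)
#' @export
kalman_step <- function(state, hr, model) {
  stopifnot(inherits(model, "hr_sigmoid"))
  if (!is.numeric(state$tc_hat) || !is.numeric(state$variance) ||
      state$variance < 0)
    stopf("state must have finite tc_hat and non-negative variance")
  v_prior <- state$variance + model$process_noise_var
  if (is.na(hr)) return(list(tc_hat = state$tc_hat, variance = v_prior))
  if (!is.finite(hr)) stopf("hr must be finite or NA")
  c_hat <- sigmoid_hr_deriv(model, state$tc_hat)
  k <- v_prior * c_hat / (c_hat^2 * v_prior + model$obs_noise_var)
  list(tc_hat = state$tc_hat + k * (hr - sigmoid_hr(model, state$tc_hat)),
       variance = (1 - k * c_hat) * v_prior)
}

#' Estimate a core-temperature series from minute heart rates
#'
#' Runs the extended Kalman filter sequentially over a minute-average
#' heart-rate series, starting from a fixed prior. The defaults — starting
#' temperature 37.0 °C with variance 0.02 °C² — are the field-deployment
#' configuration, used when no baseline core-temperature measurement is
#' available.
#'
#' Heart rates outside the sigmoid's open range are still assimilated (the
#' innovation is well defined); a warning notes how many such minutes
#' occurred. `NA` minutes propagate the time update only.
#'
#' @param hr Numeric vector of minute-average heart rates (bpm); `NA`s
#'   allowed for missing minutes.
#' @param model An [hr_sigmoid()] observation model.
#' @param start_tc Starting core temperature in °C (default 37.0).
#' @param start_variance Starting variance in °C² (default 0.02).
#' @param minute Optional minute indices (same length as `hr`); defaults to
#'   `seq_along(hr) - 1`. Indices label the output only — the filter
#'   depends on the order of the heart rates, not their clock values.
#' @param athlete_id Optional identifier stored in the result.
#'
#' @return An object of class `tc_estimate`: a data frame with columns
#'   `minute`, `hr`, `tc_est` (°C) and `variance` (°C²), one row per input
#'   minute, plus attributes `model`, `start_tc`, `start_variance`,
#'   `athlete_id`.
#' @examples
#' m <- hr_sigmoid(55, 150, 38.1, 0.55, obs_noise_var = 9)
#' est <- estimate_tc(rep(sigmoid_hr(m, 38.5), 40), m)
#' tail(est$tc_est, 1)  # converges towards 38.5
#' @export
estimate_tc <- function(hr, model, start_tc = 37.0, start_variance = 0.02,
                        minute = NULL, athlete_id = NA_character_) {
  stopifnot(inherits(model, "hr_sigmoid"))
  if (length(hr) == 0L) stopf("hr series is empty")
  if (any(!is.finite(hr) & !is.na(hr)))
    stopf("hr must contain only finite values or NA")
  if (!is.finite(start_tc) || !is.finite(start_variance) ||
      start_variance < 0)
    stopf("invalid starting state")
  minute <- minute %||% (seq_along(hr) - 1L)
  stopifnot(length(minute) == length(hr))

  out_of_range <- sum(!is.na(hr) &
                        (hr <= model$floor_hr |
                           hr >= model$floor_hr + model$amplitude))
  if (out_of_range > 0)
    warning(sprintf(
      "%d heart-rate minute(s) outside the sigmoid's open range were assimilated",
      out_of_range), call. = FALSE)

  n <- length(hr)
  tc_est <- numeric(n)
  variance <- numeric(n)
  state <- list(tc_hat = start_tc, variance = start_variance)
  for (i in seq_len(n)) {
    state <- kalman_step(state, hr[i], model)
    tc_est[i] <- state$tc_hat
    variance[i] <- state$variance
  }
  structure(
    data.frame(minute = minute, hr = hr, tc_est = tc_est,
               variance = variance),
    model = model, start_tc = start_tc, start_variance = start_variance,
    athlete_id = athlete_id,
    class = c("tc_estimate", "data.frame"))
}

#' @export
print.tc_estimate <- function(x, ...) {
  id <- attr(x, "athlete_id")
  cat("Core-temperature estimate series",
      if (!is.na(id)) paste0(" (athlete ", id, ")"), ": ",
      nrow(x), " minutes\n", sep = "")
  cat(sprintf("  start %.2f degC (var %.3g); final %.2f degC (var %.3g)\n",
              attr(x, "start_tc"), attr(x, "start_variance"),
              x$tc_est[nrow(x)], x$variance[nrow(x)]))
  invisible(x)
}

#' @export
plot.tc_estimate <- function(x, ...) {
  graphics::plot(x$minute, x$tc_est, type = "l",
                 xlab = "minute", ylab = "estimated Tc (degC)", ...)
  se <- sqrt(x$variance)
  graphics::lines(x$minute, x$tc_est + 1.96 * se, lty = 3)
  graphics::lines(x$minute, x$tc_est - 1.96 * se, lty = 3)
  invisible(x)
}
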