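#' Remove erroneous core-temperature outliers
#'
#' Deterministic replacement for manual outlier review: a Tc sample is
#' deleted (becoming a gap) if it lies outside `[low, high]` or if it is an
#' interior sample differing from both of its neighbours by more than
#' `max_step` (endpoint samples have a single neighbour and are only
#' subject to the range rule). The rule is applied repeatedly until no
#' sample violates it, which makes the operation idempotent. Heart rate is
#' untouched.
#'
#' The defaults — 35.0-42.0 °C and 0.5 °C per 10-s sample — bracket
#' physiologically attainable exercise core temperatures and the fastest
#' plausible intestinal-sensor change.
#'
#' @param trace A `raw_trace` (see [generate_cohort()]).
#' @param low,high Physiological range bounds in °C.
#' @param max_step Maximum credible change per sample in °C.
#' @return The trace with offending Tc samples removed, plus attribute
#'   `removal_log`: a data frame (`time_s`, `tc_c`, `reason`) of removals.
#' @examples
#' tr <- list(athlete_id = "a", hr = data.frame(time_s = 0:9, hr_bpm = 100),
#'            tc = data.frame(time_s = seq(0, 30, 10),
#'                            tc_c = c(37.0, 37.1, 41.8, 37.2)))
#' class(tr) <- "raw_trace"
#' cleaned <- remove_tc_outliers(tr)
#' attr(cleaned, "removal_log")
#' @export
remove_tc_outliers <- function(trace, low = 35.0, high = 42.0,
                               max_step = 0.5) {
  stopifnot(inherits(trace, "raw_trace"))
  if (low >= high) stopf("low must be < high")
  if (max_step <= 0) stopf("max_step must be > 0")
  if (nrow(trace$tc) == 0L) stopf("Tc stream is empty")

  tc <- trace$tc
  log <- data.frame(time_s = numeric(0), tc_c = numeric(0),
                    reason = character(0))
  repeat {
    v <- tc$tc_c
    n <- length(v)
    if (n == 0L) break
    range_bad <- v < low | v > high
    step_bad <- rep(FALSE, n)
    if (n >= 3L) {
      dprev <- c(Inf, abs(diff(v)))
      dnext <- c(abs(diff(v)), Inf)
      # interior samples only: a spike differs from BOTH neighbours;
      # endpoints have one neighbour and are caught by the range rule
      step_bad <- (dprev > max_step) & (dnext > max_step)
      step_bad[c(1L, n)] <- FALSE
    }
    bad <- range_bad | step_bad
    if (!any(bad)) break
    log <- rbind(log, data.frame(
      time_s = tc$time_s[bad], tc_c = v[bad],
      reason = ifelse(range_bad[bad], "out_of_range", "step")))
    tc <- tc[!bad, , drop = FALSE]
  }
  trace$tc <- tc
  attr(trace, "removal_log") <- log
  trace
}

#' Minute-average a raw trace
#'
#' Averages the 1-s heart-rate and 10-s core-temperature streams into
#' minute bins. Minute `m` covers samples with `time_s` in
#' `[t0 + 60m, t0 + 60(m+1))` (half-open), with the origin `t0` at the
#' first sample time common to both streams. A minute with no Tc samples
#' is retained with `tc = NA` (a gap for [interpolate_gaps()] to handle);
#' likewise for HR. The trailing partial minute is retained only if the
#' trace covers at least half of it.
#'
#' @param trace A `raw_trace`.
#' @return An `aligned_series`: a data frame with columns `minute`, `hr`
#'   (bpm), `tc` (°C), `tc_interpolated` (logical, all `FALSE` here), and
#'   attributes `athlete_id`, `sex`, `discipline`,
#'   `exclusion_flag` (`"none"`).
#' @export
minute_average <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  if (nrow(trace$hr) == 0L || nrow(trace$tc) == 0L)
    stopf("both streams must be non-empty")
  t0 <- max(min(trace$hr$time_s), min(trace$tc$time_s))
  t_end <- min(max(trace$hr$time_s), max(trace$tc$time_s))
  if (t_end < t0) stopf("HR and Tc streams do not overlap in time")

  n_min <- floor((t_end - t0) / 60) + 1L
  # drop the trailing partial minute unless >= 50% covered
  last_cover <- (t_end - t0 + 1) - 60 * (n_min - 1L)
  if (n_min > 1L && last_cover < 30) n_min <- n_min - 1L

  bin <- function(df, col) {
    m <- floor((df$time_s - t0) / 60)
    ok <- m >= 0 & m < n_min
    means <- tapply(df[[col]][ok], factor(m[ok], levels = 0:(n_min - 1L)),
                    mean)
    as.numeric(means)
  }
  out <- data.frame(minute = 0:(n_min - 1L),
                    hr = bin(trace$hr, "hr_bpm"),
                    tc = bin(trace$tc, "tc_c"),
                    tc_interpolated = FALSE)
  structure(out, athlete_id = trace$athlete_id, sex = trace$sex,
            discipline = trace$discipline, exclusion_flag = "none",
            class = c("aligned_series", "data.frame"))
}

#' Fill short gaps in a minute-averaged series
#'
#' Internal runs of missing Tc minutes strictly shorter than `max_gap_min`
#' are filled by linear interpolation between the flanking observed minutes
#' and flagged `tc_interpolated`. Longer runs are left unfilled and the
#' series' `exclusion_flag` is set to `"long_gap_unresolved"` — unless
#' `override_long_gaps = TRUE`, which accepts the linear fill for them too
#' (the automated counterpart of a manual curve review), still flagging the
#' filled minutes. Missing HR minutes are treated by the same rule
#' (symmetric treatment; HR gaps are rare and short in practice). Leading
#' and trailing missing minutes are trimmed.
#'
#' @param series An `aligned_series` from [minute_average()].
#' @param max_gap_min Longest gap (minutes) filled without review;
#'   default 5.
#' @param override_long_gaps Accept the linear fill for gaps of
#'   `max_gap_min` or longer instead of flagging the series.
#' @return The series with gaps handled; attribute `interpolation_log`
#'   records each filled run (`variable`, `start_minute`, `length`).
#' @export
interpolate_gaps <- function(series, max_gap_min = 5,
                             override_long_gaps = FALSE) {
  stopifnot(inherits(series, "aligned_series"))
  at <- attributes(series)
  df <- as.data.frame(series)
  log <- data.frame(variable = character(0), start_minute = integer(0),
                    length = integer(0))
  flag <- at$exclusion_flag %||% "none"

  # trim leading/trailing minutes missing either variable
  present <- !is.na(df$hr) & !is.na(df$tc)
  first <- match(TRUE, present)
  last <- nrow(df) + 1L - match(TRUE, rev(present))
  if (is.na(first)) stopf("series has no complete minute")
  df <- df[first:last, , drop = FALSE]

  fill <- function(x, which_var) {
    miss <- is.na(x)
    if (!any(miss)) return(list(x = x, interp = rep(FALSE, length(x))))
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interp <- rep(FALSE, length(x))
    for (j in which(r$values)) {
      len <- r$lengths[j]
      if (len < max_gap_min || override_long_gaps) {
        lo <- starts[j] - 1L; hi <- ends[j] + 1L
        x[starts[j]:ends[j]] <- x[lo] +
          (x[hi] - x[lo]) * seq_len(len) / (len + 1L)
        interp[starts[j]:ends[j]] <- TRUE
        log <<- rbind(log, data.frame(variable = which_var,
                                      start_minute = df$minute[starts[j]],
                                      length = len))
      } else {
        flag <<- "long_gap_unresolved"
      }
    }
    list(x = x, interp = interp)
  }
  tc_f <- fill(df$tc, "tc")
  hr_f <- fill(df$hr, "hr")
  df$tc <- tc_f$x
  df$hr <- hr_f$x
  df$tc_interpolated <- df$tc_interpolated | tc_f$interp

  structure(df, athlete_id = at$athlete_id, sex = at$sex,
            discipline = at$discipline, exclusion_flag = flag,
            interpolation_log = log,
            class = c("aligned_series", "data.frame"))
}

#' Preprocess one raw trace end to end
#'
#' Outlier removal, minute averaging and gap interpolation in sequence,
#' with the defaults documented in the individual steps.
#'
#' @inheritParams remove_tc_outliers
#' @inheritParams interpolate_gaps
#' @return An `aligned_series`.
#' @export
preprocess_trace <- function(trace, low = 35.0, high = 42.0,
                             max_step = 0.5, max_gap_min = 5,
                             override_long_gaps = FALSE) {
  interpolate_gaps(minute_average(remove_tc_outliers(trace, low, high,
                                                     max_step)),
                   max_gap_min = max_gap_min,
                   override_long_gaps = override_long_gaps)
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("Aligned series %s: %d minutes (%d Tc-interpolated), exclusion flag '%s'\n",
              attr(x, "athlete_id"), nrow(x), sum(x$tc_interpolated),
              attr(x, "exclusion_flag")))
  invisible(x)
}

#' Combine aligned series into one table
#'
#' Row-binds per-athlete [minute_average()] output into the `aligned.csv`
#' layout: `athlete_id,minute,hr_bpm,tc_c,tc_interpolated,excluded`.
#'
#' @param series_list List of `aligned_series`.
#' @return A data frame in the aligned layout.
#' @export
aligned_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(athlete_id = attr(s, "athlete_id"), minute = s$minute,
               hr_bpm = s$hr, tc_c = s$tc,
               tc_interpolated = s$tc_interpolated,
               excluded = attr(s, "exclusion_flag") != "none")))
}
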