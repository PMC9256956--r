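# Shared fixtures built in code.

# canonical synthetic observation model used across tests
test_model <- function(obs_noise_var = 9, process_noise_var = 0.001) {
  hr_sigmoid(floor_hr = 60, amplitude = 140, midpoint = 38.2, scale = 0.6,
             obs_noise_var = obs_noise_var,
             process_noise_var = process_noise_var)
}

# assemble a raw_trace by hand from sample vectors
make_trace <- function(hr_time, hr, tc_time, tc, id = "t01",
                       sex = "female", discipline = "endurance") {
  structure(list(athlete_id = id, sex = sex, discipline = discipline,
                 hr = data.frame(time_s = hr_time, hr_bpm = hr),
                 tc = data.frame(time_s = tc_time, tc_c = tc)),
            class = "raw_trace")
}

# a paired panel straight from vectors
make_panel <- function(athlete_id, tc, tc_est, minute = NULL,
                       sex = NULL, discipline = NULL) {
  df <- data.frame(athlete_id = athlete_id,
                   minute = minute %||% stats::ave(seq_along(tc),
                                                   athlete_id,
                                                   FUN = seq_along),
                   tc = tc, tc_est = tc_est)
  df$diff <- df$tc_est - df$tc
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(discipline)) df$discipline <- discipline
  structure(df, class = c("paired_panel", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent scalar-recurrence oracle for the filter: a direct loop over
# the published update equations, written separately from the package code
ekf_oracle <- function(hr, d, a, cc, b, s2, g2, x0 = 37, v0 = 0.02) {
  x <- x0; v <- v0
  out <- numeric(length(hr))
  for (i in seq_along(hr)) {
    vp <- v + g2
    s <- 1 / (1 + exp(-(x - cc) / b))
    m <- d + a * s
    mp <- a * s * (1 - s) / b
    k <- vp * mp / (mp^2 * vp + s2)
    x <- x + k * (hr[i] - m)
    v <- (1 - k * mp) * vp
    out[i] <- x
  }
  out
}
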