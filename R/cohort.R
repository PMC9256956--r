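#' Specification of a synthetic athlete cohort
#'
#' Collects the parameters that shape a simulated cohort of incremental
#' heat-stress exercise tests: cohort distributions of baseline/peak heart
#' rate, test duration and baseline/peak core temperature; the exercise
#' protocol (warm-up plateau at a fraction of maximal HR, then stage-wise
#' workload increments); sensor cadences and noise; and the number of data
#' defects (gaps, outlier spikes) injected per trace.
#'
#' The distribution defaults describe an elite-athlete cohort performing a
#' 20-min warm-up at ~70% of maximal HR followed by 3-min stages of +5%
#' workload until exhaustion in hot, humid conditions: baseline HR
#' 82 ± 14 bpm rising to 182 ± 12 bpm, test duration 44 ± 10 min, core
#' temperature 37.1 ± 0.4 °C at baseline rising to 38.9 ± 0.6 °C at peak.
#'
#' @param n_athletes Number of athletes to simulate.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param baseline_hr_mean,baseline_hr_sd Baseline HR distribution (bpm).
#' @param peak_hr_mean,peak_hr_sd Peak HR distribution (bpm).
#' @param duration_mean,duration_sd Test duration distribution (minutes).
#' @param baseline_tc_mean,baseline_tc_sd Baseline core temperature (°C).
#' @param peak_tc_mean,peak_tc_sd Peak core temperature (°C).
#' @param warmup_min Warm-up length in minutes.
#' @param warmup_hr_fraction Warm-up HR as a fraction of maximal HR,
#'   strictly between 0 and 1.
#' @param stage_min Length of each incremental stage in minutes.
#' @param stage_increment Workload increment per stage as a fraction.
#' @param tc_time_constant First-order lag time constant of the core
#'   temperature response, minutes.
#' @param hr_noise_sd HR sensor noise SD (bpm); 2 bpm emulates a chest
#'   strap.
#' @param tc_noise_sd Tc sensor noise SD (°C); 0.05 °C emulates a
#'   telemetric capsule.
#' @param gap_rate Number of contiguous missing-data gaps injected into
#'   each Tc stream (a count, applied exactly); gap lengths are drawn
#'   uniformly from 1-8 min so that both interpolation branches (< 5 min
#'   and >= 5 min) occur across a cohort.
#' @param outlier_rate Number of single-sample outlier spikes injected per
#'   trace (a count, applied exactly): +2 to +5 °C on Tc, ±60 bpm on HR.
#' @param sex_fraction_male Probability an athlete is male.
#' @param discipline_mix Named proportions over the sport-discipline
#'   groups `endurance`, `mixed`, `power`, `skill`; must sum to 1.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_athletes = 101, seed = 1,
                        baseline_hr_mean = 82, baseline_hr_sd = 14,
                        peak_hr_mean = 182, peak_hr_sd = 12,
                        duration_mean = 44, duration_sd = 10,
                        baseline_tc_mean = 37.1, baseline_tc_sd = 0.4,
                        peak_tc_mean = 38.9, peak_tc_sd = 0.6,
                        warmup_min = 20, warmup_hr_fraction = 0.70,
                        stage_min = 3, stage_increment = 0.05,
                        tc_time_constant = 10,
                        hr_noise_sd = 2, tc_noise_sd = 0.05,
                        gap_rate = 1, outlier_rate = 2,
                        sex_fraction_male = 49 / 101,
                        discipline_mix = c(endurance = 27, mixed = 28,
                                           power = 11, skill = 35) / 101) {
  spec <- as.list(environment())
  sds <- c(baseline_hr_sd, peak_hr_sd, duration_sd, baseline_tc_sd,
           peak_tc_sd, hr_noise_sd, tc_noise_sd)
  if (n_athletes < 1 || n_athletes != round(n_athletes))
    stopf("n_athletes must be a positive integer")
  if (any(sds < 0)) stopf("all SDs must be >= 0")
  if (duration_mean <= warmup_min)
    stopf("duration_mean must exceed warmup_min")
  if (warmup_hr_fraction <= 0 || warmup_hr_fraction >= 1)
    stopf("warmup_hr_fraction must be strictly between 0 and 1")
  if (gap_rate < 0 || outlier_rate < 0)
    stopf("gap_rate and outlier_rate must be >= 0")
  if (sex_fraction_male < 0 || sex_fraction_male > 1)
    stopf("sex_fraction_male must be in [0, 1]")
  if (!setequal(names(discipline_mix),
                c("endurance", "mixed", "power", "skill")) ||
      any(discipline_mix < 0) ||
      abs(sum(discipline_mix) - 1) > 1e-8)
    stopf("discipline_mix must be proportions over endurance/mixed/power/skill summing to 1")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d athletes, seed %d\n",
              x$n_athletes, x$seed))
  cat(sprintf("  HR %g+/-%g -> %g+/-%g bpm; Tc %g+/-%g -> %g+/-%g degC; duration %g+/-%g min\n",
              x$baseline_hr_mean, x$baseline_hr_sd, x$peak_hr_mean,
              x$peak_hr_sd, x$baseline_tc_mean, x$baseline_tc_sd,
              x$peak_tc_mean, x$peak_tc_sd, x$duration_mean, x$duration_sd))
  cat(sprintf("  protocol: %g min warm-up at %.0f%% HRmax, +%.0f%% workload per %g min stage\n",
              x$warmup_min, 100 * x$warmup_hr_fraction,
              100 * x$stage_increment, x$stage_min))
  invisible(x)
}

# Deterministic protocol truth for one athlete.
# HR: ramp from baseline to the warm-up plateau (70% HRmax) over the first
# 3 min, plateau to warmup_min, then stage-wise steps reaching peak HR at
# exhaustion, smoothed by a short first-order lag (30 s) so minute means
# are realistic. Tc: first-order lag towards a workload-driven equilibrium,
# scaled so the drawn peak Tc is attained exactly at the drawn duration.
athlete_truth <- function(dur_s, baseline_hr, peak_hr, baseline_tc, peak_tc,
                          warmup_min, warmup_hr_fraction, stage_min,
                          tc_time_constant) {
  t <- seq(0, dur_s)                     # 1-s grid, seconds
  warm_s <- warmup_min * 60
  plateau <- warmup_hr_fraction * peak_hr
  n_stage <- max(1L, ceiling((dur_s - warm_s) / (stage_min * 60)))

  hr_target <- ifelse(
    t < 180, baseline_hr + (plateau - baseline_hr) * t / 180,
    ifelse(t <= warm_s, plateau,
           plateau + (peak_hr - plateau) *
             pmin(ceiling((t - warm_s) / (stage_min * 60)), n_stage) /
             n_stage))
  # 30-s first-order lag smooths the stage steps:
  # y_t = (1-a) x_t + a y_{t-1}, via stats::filter's recursive form
  a_hr <- exp(-1 / 30)
  hr_true <- as.numeric(stats::filter((1 - a_hr) * hr_target, a_hr,
                                      method = "recursive",
                                      init = baseline_hr))

  # relative workload proxy in [0, 1] from the HR target
  u <- (hr_target - baseline_hr) / (peak_hr - baseline_hr)
  # g' = (u - g)/tau on the 1-s grid; exact exponential step
  a <- exp(-1 / (tc_time_constant * 60))
  g <- as.numeric(stats::filter((1 - a) * u, a, method = "recursive",
                                init = 0))
  g <- c(0, g[-length(g)])               # g(0) = 0 at t = 0
  sc <- (peak_tc - baseline_tc) / g[length(g)]
  tc_true <- baseline_tc + sc * g
  list(time_s = t, hr_true = hr_true, tc_true = tc_true)
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-athlete baseline/peak targets from the cohort distributions
#' (redrawing any athlete whose peak does not exceed their baseline),
#' builds smooth deterministic truth profiles — a warm-up plateau plus
#' stage-wise heart-rate ramp, and a first-order-lag core-temperature rise
#' reaching the drawn peak at the drawn duration — then records noisy
#' sensor streams at the wearable cadences (HR every 1 s, Tc every 10 s)
#' and injects the configured number of missing-data gaps and outlier
#' spikes.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `raw_trace` objects, one per athlete. Each is a list
#'   with `athlete_id`, `sex`, `discipline`, data frames `hr` (`time_s`,
#'   `hr_bpm`) and `tc` (`time_s`, `tc_c`), and a `truth` data frame
#'   (`time_s`, `hr_true`, `tc_true`) retained for validation work.
#' @examples
#' traces <- generate_cohort(cohort_spec(n_athletes = 2, seed = 7))
#' traces[[1]]$athlete_id
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_athletes), function(i) {
      generate_athlete(spec, sprintf("ath%03d", i))
    })
  })
}

generate_athlete <- function(spec, athlete_id) {
  # rejection sampling: peak must exceed baseline (HR and Tc), duration
  # must exceed the warm-up
  repeat {
    baseline_hr <- stats::rnorm(1, spec$baseline_hr_mean, spec$baseline_hr_sd)
    peak_hr <- stats::rnorm(1, spec$peak_hr_mean, spec$peak_hr_sd)
    if (peak_hr > baseline_hr + 20) break
  }
  repeat {
    baseline_tc <- stats::rnorm(1, spec$baseline_tc_mean, spec$baseline_tc_sd)
    peak_tc <- stats::rnorm(1, spec$peak_tc_mean, spec$peak_tc_sd)
    if (peak_tc > baseline_tc + 0.2) break
  }
  repeat {
    duration <- stats::rnorm(1, spec$duration_mean, spec$duration_sd)
    if (duration > spec$warmup_min + spec$stage_min) break
  }
  dur_s <- round(duration * 60)

  sex <- if (stats::runif(1) < spec$sex_fraction_male) "male" else "female"
  discipline <- sample(names(spec$discipline_mix), 1,
                       prob = spec$discipline_mix)

  tr <- athlete_truth(dur_s, baseline_hr, peak_hr, baseline_tc, peak_tc,
                      spec$warmup_min, spec$warmup_hr_fraction,
                      spec$stage_min, spec$tc_time_constant)

  hr_time <- tr$time_s
  tc_idx <- seq(1, length(tr$time_s), by = 10)   # 10-s cadence
  tc_time <- tr$time_s[tc_idx]

  hr_rec <- tr$hr_true +
    if (spec$hr_noise_sd > 0)
      stats::rnorm(length(hr_time), 0, spec$hr_noise_sd) else 0
  tc_rec <- tr$tc_true[tc_idx] +
    if (spec$tc_noise_sd > 0)
      stats::rnorm(length(tc_time), 0, spec$tc_noise_sd) else 0

  # gaps: contiguous runs of missing Tc samples, 1-8 min long, interior,
  # placed without touching each other so the configured count is exact
  n_gap <- round(spec$gap_rate)
  keep_tc <- rep(TRUE, length(tc_time))
  if (n_gap > 0) {
    for (g in seq_len(n_gap)) {
      gap_min <- sample(1:8, 1)
      gap_len <- gap_min * 6                      # samples at 10-s cadence
      lo <- 7                                      # keep the first minute
      hi <- length(tc_time) - gap_len - 6          # and the last minute
      if (hi <= lo) next
      for (try in 1:50) {
        start <- sample(lo:hi, 1)
        span <- max(1, start - 1):min(length(tc_time),
                                      start + gap_len)
        if (all(keep_tc[span])) {
          keep_tc[start:(start + gap_len - 1)] <- FALSE
          break
        }
      }
    }
  }

  # outlier spikes: single retained samples, split between the two streams
  n_out <- round(spec$outlier_rate)
  if (n_out > 0) {
    streams <- sample(c("tc", "hr"), n_out, replace = TRUE)
    tc_pool <- which(keep_tc)
    hr_pool <- seq_along(hr_rec)
    for (s in streams) {
      if (s == "tc" && length(tc_pool) > 0) {
        j <- tc_pool[sample.int(length(tc_pool), 1)]
        tc_pool <- setdiff(tc_pool, j)
        tc_rec[j] <- tc_rec[j] + stats::runif(1, 2, 5)
      } else {
        j <- hr_pool[sample.int(length(hr_pool), 1)]
        hr_pool <- setdiff(hr_pool, j)
        hr_rec[j] <- hr_rec[j] + sample(c(-60, 60), 1)
      }
    }
  }

  structure(
    list(athlete_id = athlete_id, sex = sex, discipline = discipline,
         hr = data.frame(time_s = hr_time, hr_bpm = hr_rec),
         tc = data.frame(time_s = tc_time[keep_tc], tc_c = tc_rec[keep_tc]),
         truth = data.frame(time_s = tr$time_s, hr_true = tr$hr_true,
                            tc_true = tr$tc_true)),
    class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("Raw trace %s (%s, %s): %d HR samples @1 s, %d Tc samples @10 s\n",
              x$athlete_id, x$sex, x$discipline, nrow(x$hr), nrow(x$tc)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `hr.csv` (`athlete_id,time_s,hr_bpm`), `tc.csv`
#' (`athlete_id,time_s,tc_c`) and `athletes.csv`
#' (`athlete_id,sex,discipline`) into `dir`. Missing samples are absent
#' rows, not `NA` rows.
#'
#' @param traces List of traces from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the three files.
#' @export
write_cohort <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hr <- do.call(rbind, lapply(traces, function(x)
    cbind(athlete_id = x$athlete_id, x$hr)))
  tc <- do.call(rbind, lapply(traces, function(x)
    cbind(athlete_id = x$athlete_id, x$tc)))
  ath <- do.call(rbind, lapply(traces, function(x)
    data.frame(athlete_id = x$athlete_id, sex = x$sex,
               discipline = x$discipline)))
  paths <- file.path(dir, c("hr.csv", "tc.csv", "athletes.csv"))
  utils::write.csv(hr, paths[1], row.names = FALSE)
  utils::write.csv(tc, paths[2], row.names = FALSE)
  utils::write.csv(ath, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]: reads `hr.csv`, `tc.csv` and `athletes.csv`
#' from `dir` and reassembles per-athlete traces.
#'
#' @param dir Directory holding the three CSV files.
#' @return A list of `raw_trace` objects (without `truth`).
#' @export
read_cohort <- function(dir) {
  hr <- utils::read.csv(file.path(dir, "hr.csv"))
  tc <- utils::read.csv(file.path(dir, "tc.csv"))
  ath <- utils::read.csv(file.path(dir, "athletes.csv"))
  lapply(seq_len(nrow(ath)), function(i) {
    id <- ath$athlete_id[i]
    structure(
      list(athlete_id = id, sex = ath$sex[i], discipline = ath$discipline[i],
           hr = hr[hr$athlete_id == id, c("time_s", "hr_bpm")],
           tc = tc[tc$athlete_id == id, c("time_s", "tc_c")],
           truth = NULL),
      class = "raw_trace")
  })
}
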