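test_that("a single hot spike is removed and the rest survives", {
  tr <- make_trace(hr_time = 0:39, hr = rep(100, 40),
                   tc_time = c(0, 10, 20, 30),
                   tc = c(37.0, 37.1, 41.8, 37.2))
  out <- remove_tc_outliers(tr, max_step = 0.5)
  expect_equal(out$tc$tc_c, c(37.0, 37.1, 37.2))
  log <- attr(out, "removal_log")
  expect_equal(nrow(log), 1)
  expect_equal(log$tc_c, 41.8)
  expect_identical(out$hr, tr$hr)  # HR untouched
})

test_that("clean and constant streams pass through unchanged", {
  tr <- make_trace(0:59, rep(110, 60), seq(0, 50, 10),
                   c(37.0, 37.1, 37.2, 37.25, 37.3, 37.4))
  out <- remove_tc_outliers(tr)
  expect_equal(out$tc, tr$tc)
  expect_equal(nrow(attr(out, "removal_log")), 0)

  flat <- make_trace(0:59, rep(110, 60), seq(0, 50, 10), rep(37, 6))
  expect_equal(remove_tc_outliers(flat)$tc$tc_c, rep(37, 6))
})

test_that("range violations go even when step-consistent with neighbours", {
  tr <- make_trace(0:59, rep(110, 60), seq(0, 50, 10),
                   c(42.4, 42.5, 42.6, 42.5, 42.4, 42.3))
  out <- remove_tc_outliers(tr, low = 35, high = 42)
  expect_equal(nrow(out$tc), 0)
  expect_true(all(attr(out, "removal_log")$reason == "out_of_range"))
})

test_that("outlier removal is idempotent", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    tc <- 37 + cumsum(rnorm(n, 0.01, 0.05))
    spikes <- sample(2:(n - 1), 3)
    tc[spikes] <- tc[spikes] + runif(3, 1, 6)
    tr <- make_trace(0:(n * 10 - 1), rep(100, n * 10),
                     seq(0, (n - 1) * 10, 10), tc)
    once <- remove_tc_outliers(tr)
    twice <- remove_tc_outliers(once)
    expect_equal(twice$tc, once$tc)
    expect_equal(nrow(attr(twice, "removal_log")), 0)
  }
})

test_that("minute averaging bins half-open minutes from the common origin", {
  # constant HR over two full minutes
  tr <- make_trace(0:119, rep(100, 120), seq(0, 110, 10), rep(37, 12))
  ma <- minute_average(tr)
  expect_equal(ma$hr, c(100, 100))
  expect_equal(ma$tc, c(37, 37))
  expect_equal(ma$minute, c(0, 1))

  # HR 1..60 bpm in minute 0: arithmetic mean 30.5
  tr2 <- make_trace(0:59, 1:60, seq(0, 50, 10), rep(37, 6))
  expect_equal(minute_average(tr2)$hr, 30.5)

  # 10-s cadence: exactly 6 Tc samples contribute to a full minute
  tr3 <- make_trace(0:59, rep(80, 60), seq(0, 50, 10),
                    c(37.0, 37.1, 37.2, 37.3, 37.4, 37.5))
  expect_equal(minute_average(tr3)$tc, mean(c(37.0, 37.1, 37.2,
                                              37.3, 37.4, 37.5)))
})

test_that("trailing partial minutes follow the 50% coverage rule", {
  # 90 s of data: trailing 30 s = 50% coverage, retained
  tr <- make_trace(0:89, rep(100, 90), seq(0, 90, 10), rep(37, 10))
  expect_equal(nrow(minute_average(tr)), 2)
  # 75 s of data: trailing 15 s < 50%, dropped
  tr2 <- make_trace(0:74, rep(100, 75), seq(0, 70, 10), rep(37, 8))
  expect_equal(nrow(minute_average(tr2)), 1)
  expect_error(minute_average(make_trace(0:9, rep(100, 10), 500, 37)),
               "overlap")
})

test_that("a minute without Tc samples becomes an internal gap", {
  tc_t <- c(seq(0, 50, 10), seq(120, 170, 10))   # minute 1 missing
  tr <- make_trace(0:179, rep(100, 180), tc_t, rep(37.2, 12))
  ma <- minute_average(tr)
  expect_equal(nrow(ma), 3)
  expect_true(is.na(ma$tc[2]))
  expect_false(is.na(ma$hr[2]))
})

test_that("short gaps are filled linearly and flagged", {
  tr <- make_trace(0:299, rep(100, 300),
                   c(seq(0, 50, 10), seq(180, 290, 10)),
                   c(rep(37.0, 6), rep(37.3, 12)))
  ma <- minute_average(tr)          # minutes 1-2 have no Tc
  out <- interpolate_gaps(ma)
  expect_equal(out$tc, c(37.0, 37.1, 37.2, 37.3, 37.3),
               tolerance = 1e-12)
  expect_equal(out$tc_interpolated, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "exclusion_flag"), "none")
  log <- attr(out, "interpolation_log")
  expect_equal(log$length[log$variable == "tc"], 2)
})

test_that("long gaps stay unfilled unless explicitly overridden", {
  # 6 missing Tc minutes between observed minutes
  tc_t <- c(seq(0, 50, 10), seq(420, 470, 10))
  tr <- make_trace(0:479, rep(100, 480), tc_t,
                   c(rep(37.0, 6), rep(37.7, 6)))
  ma <- minute_average(tr)
  out <- interpolate_gaps(ma)
  expect_equal(attr(out, "exclusion_flag"), "long_gap_unresolved")
  expect_equal(sum(is.na(out$tc)), 6)
  # override accepts the linear fill, still flags the minutes
  ov <- interpolate_gaps(ma, override_long_gaps = TRUE)
  expect_equal(attr(ov, "exclusion_flag"), "none")
  expect_false(any(is.na(ov$tc)))
  expect_equal(sum(ov$tc_interpolated), 6)
})

test_that("gap-free series are unchanged and fills stay within flanks", {
  tr <- make_trace(0:179, rep(100, 180), seq(0, 170, 10),
                   37 + seq(0, 0.17, 0.01))
  ma <- minute_average(tr)
  out <- interpolate_gaps(ma)
  expect_equal(out$tc, ma$tc)
  expect_equal(out$hr, ma$hr)
  expect_equal(out$tc_interpolated, ma$tc_interpolated)

  set.seed(17)
  for (rep in 1:10) {
    n <- 20
    tc <- sort(37 + cumsum(abs(rnorm(n, 0.05, 0.05))))
    gap <- sample(3:(n - 3), 1)
    drop <- gap:(gap + sample(1:3, 1))
    df <- data.frame(minute = 0:(n - 1), hr = rep(100, n), tc = tc,
                     tc_interpolated = FALSE)
    df$tc[drop] <- NA
    series <- structure(df, athlete_id = "p", sex = "female",
                        discipline = "mixed", exclusion_flag = "none",
                        class = c("aligned_series", "data.frame"))
    out <- interpolate_gaps(series)
    # monotone flanks: interpolated values between the flanking observed
    expect_true(all(out$tc[drop] >= tc[min(drop) - 1] &
                      out$tc[drop] <= tc[max(drop) + 1]))
  }
})

test_that("retained minutes never exceed the trace duration budget", {
  spec <- cohort_spec(n_athletes = 3, seed = 41)
  for (tr in generate_cohort(spec)) {
    s <- preprocess_trace(tr)
    dur_min <- floor(nrow(tr$hr) / 60)
    expect_lte(nrow(s), dur_min + 1)
  }
})
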