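test_that("bias and its t-test match direct formula computation", {
  # perfect agreement
  p0 <- make_panel(rep("a", 4), c(37, 38, 38.5, 39), c(37, 38, 38.5, 39))
  b0 <- bias_and_ttest(p0)
  expect_equal(b0$bias, 0)
  expect_equal(b0$t_stat, 0)

  # constant offset: bias = offset, zero spread, degenerate t
  p1 <- make_panel(rep("a", 5), rep(38, 5), rep(38.2, 5))
  b1 <- bias_and_ttest(p1)
  expect_equal(b1$bias, 0.2)
  expect_equal(b1$sd_diff, 0)
  expect_true(b1$degenerate)
  expect_lte(b1$p_value, .Machine$double.xmin)

  # five hand-listed diffs; frozen textbook-formula values:
  # mean 0.08, sd 0.182345825288105, t 0.981022943175945,
  # p 0.382125789995751
  d <- c(0.1, -0.2, 0.3, 0.05, 0.15)
  p2 <- make_panel(rep("a", 5), rep(38, 5), 38 + d)
  b2 <- bias_and_ttest(p2)
  expect_equal(b2$bias, 0.08, tolerance = 1e-10)
  expect_equal(b2$sd_diff, 0.182345825288105, tolerance = 1e-10)
  expect_equal(b2$t_stat, 0.981022943175945, tolerance = 1e-10)
  expect_equal(b2$p_value, 0.382125789995751, tolerance = 1e-10)
})

test_that("repeated-measures LoA reproduces the variance-components oracle", {
  # 3 athletes with unbalanced diffs; oracle computed step by step
  # independently (frozen): MSB 0.0269444444444444, MSW 0.0075,
  # n0 2.88888888888889, between 0.00673076923076923,
  # total SD 0.119292787840545, half-width 0.233813864167468
  d <- c(0.1, 0.2, 0.3, 0.0, 0.1, 0.25, 0.35, 0.15, 0.25)
  id <- c("A", "A", "A", "B", "B", "C", "C", "C", "C")
  p <- make_panel(id, rep(38, 9), 38 + d)
  l <- loa_repeated_measures(p)
  expect_equal(l$msb, 0.0269444444444444, tolerance = 1e-10)
  expect_equal(l$msw, 0.0075, tolerance = 1e-10)
  expect_equal(l$between_var, 0.00673076923076923, tolerance = 1e-10)
  expect_equal(l$total_sd, 0.119292787840545, tolerance = 1e-10)
  expect_equal(l$loa_half_width, 0.233813864167468, tolerance = 1e-10)
  # inflation: never below the within-athlete-only spread
  expect_gte(l$loa_half_width, 1.96 * sqrt(l$msw))
})

test_that("LoA reduces to classic Bland-Altman with one record each", {
  d <- c(0.12, -0.05, 0.3, 0.08, -0.2)
  p <- make_panel(paste0("a", 1:5), rep(38, 5), 38 + d)
  l <- loa_repeated_measures(p)
  expect_equal(l$loa_half_width, 1.96 * sd(d), tolerance = 1e-12)
  # all diffs equal: zero half-width
  pe <- make_panel(c("a", "a", "b", "b"), rep(38, 4), rep(38.1, 4))
  expect_equal(loa_repeated_measures(pe)$loa_half_width, 0)
})

test_that("pearson matches the product-moment formula", {
  p <- make_panel(rep("a", 6),
                  c(37.0, 37.5, 38.0, 38.5, 39.0, 39.2),
                  c(37.2, 37.4, 38.1, 38.3, 39.2, 39.0))
  expect_equal(pearson(p), 0.975880290989802, tolerance = 1e-10)
  ident <- make_panel(rep("a", 4), c(37, 38, 38.5, 39), c(37, 38, 38.5, 39))
  expect_equal(pearson(ident), 1)
  anti <- make_panel(rep("a", 4), c(37, 38, 38.5, 39),
                     75 - c(37, 38, 38.5, 39))
  expect_equal(pearson(anti), -1)
  flat <- make_panel(rep("a", 4), rep(38, 4), c(37, 38, 38.5, 39))
  expect_error(pearson(flat), "zero variance")
})

test_that("weighted RMSE weights athletes by duration", {
  # two athletes, diffs {0.1, 0.1} and {0.4}: (2*0.1 + 1*0.4)/3 = 0.2
  p <- make_panel(c("a", "a", "b"), rep(38, 3), 38 + c(0.1, 0.1, 0.4))
  w <- weighted_rmse(p)
  expect_equal(w$rmse_mean, 0.2, tolerance = 1e-12)
  expect_equal(as.numeric(w$per_athlete), c(0.1, 0.4))

  perfect <- make_panel(c("a", "b"), c(38, 38.5), c(38, 38.5))
  expect_equal(weighted_rmse(perfect)$rmse_mean, 0)

  const <- make_panel(c("a", "a", "b", "b", "b"), rep(38, 5),
                      rep(38 - 0.3, 5))
  wc <- weighted_rmse(const)
  expect_equal(wc$rmse_mean, 0.3)
  expect_equal(wc$rmse_sd, 0)

  # equal durations and equal per-athlete RMSE: pooled root mean square
  pq <- make_panel(c("a", "a", "b", "b"), rep(38, 4),
                   38 + c(0.1, -0.1, -0.1, 0.1))
  expect_equal(weighted_rmse(pq)$rmse_mean, sqrt(mean(c(0.1, -0.1,
                                                        -0.1, 0.1)^2)))
})

test_that("agreement statistics ignore record and athlete ordering", {
  set.seed(23)
  n <- 60
  id <- sample(paste0("a", 1:6), n, replace = TRUE)
  tc <- runif(n, 37, 39.5)
  p <- make_panel(id, tc, tc + rnorm(n, 0.1, 0.2))
  perm <- sample(n)
  ps <- structure(p[perm, ], class = class(p))
  expect_equal(bias_and_ttest(ps)$t_stat, bias_and_ttest(p)$t_stat)
  expect_equal(loa_repeated_measures(ps)$loa_half_width,
               loa_repeated_measures(p)$loa_half_width)
  expect_equal(weighted_rmse(ps)$rmse_mean, weighted_rmse(p)$rmse_mean)
  expect_equal(pearson(ps), pearson(p))
})

test_that("the peak panel pairs independent per-athlete maxima", {
  # interior maximum in tc, endpoint maximum in tc_est
  p <- make_panel(rep(c("a", "b"), each = 4),
                  c(37.0, 38.6, 38.2, 38.0, 37.2, 37.9, 38.4, 38.5),
                  c(37.1, 37.8, 38.1, 38.3, 37.0, 37.7, 38.6, 38.2),
                  minute = c(0:3, 0:3))
  pk <- peak_panel(p)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$tc[pk$athlete_id == "a"], 38.6)   # interior max
  expect_equal(pk$tc_est[pk$athlete_id == "a"], 38.3)
  expect_equal(pk$tc[pk$athlete_id == "b"], 38.5)   # endpoint max
  expect_equal(pk$tc_est[pk$athlete_id == "b"], 38.6)
  expect_equal(pk$diff, pk$tc_est - pk$tc)
})

test_that("subgroup ANOVA matches hand computation and handles groups", {
  # textbook 3-group example: groups (1,2,3), (2,3,4), (4,5,6)
  # frozen hand values: F = 7, p = 0.027
  y <- c(1, 2, 3, 2, 3, 4, 4, 5, 6)
  names(y) <- paste0("a", 1:9)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  names(g) <- names(y)
  res <- subgroup_anova(y, g)
  expect_equal(res$F, 7, tolerance = 1e-10)
  expect_equal(res$p_value, 0.027, tolerance = 1e-3)

  # identical group values: F = 0
  y0 <- rep(c(1, 2), each = 3); names(y0) <- paste0("b", 1:6)
  g0 <- rep(c("x", "y", "x", "y"), length.out = 6); names(g0) <- names(y0)
  y00 <- rep(0.5, 6); names(y00) <- names(y0)
  expect_equal(subgroup_anova(y00, g0)$F, 0)

  # groups with < 2 members are excluded with a notice
  y2 <- c(1, 2, 3, 4, 9); names(y2) <- paste0("c", 1:5)
  g2 <- c("m", "m", "f", "f", "solo"); names(g2) <- names(y2)
  expect_message(res2 <- subgroup_anova(y2, g2), "solo")
  expect_equal(sort(res2$groups_used), c("f", "m"))
})

test_that("null subgroup p-values are uniform (type-I error control)", {
  set.seed(67)
  reps <- 400
  pvals <- replicate(reps, {
    y <- rnorm(24); names(y) <- paste0("a", 1:24)
    g <- rep(c("e", "m", "p", "s"), each = 6); names(g) <- names(y)
    subgroup_anova(y, g)$p_value
  })
  # rejection rate at alpha = 0.05 within binomial 3 SE
  expect_lt(abs(mean(pvals < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / reps))
  # and gross uniformity via the KS statistic
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("agreement_report assembles all statistics coherently", {
  set.seed(29)
  id <- rep(paste0("a", 1:5), times = c(30, 40, 25, 35, 20))
  tc <- 37 + cumsum(runif(length(id), 0, 0.02))
  p <- make_panel(id, tc, tc + rnorm(length(id), 0.15, 0.2))
  r <- agreement_report(p, "all_data")
  expect_equal(r$bias, mean(p$diff))
  expect_equal(r$n_athletes, 5)
  expect_gte(r$loa_half_width, 0)
  expect_true(r$pearson_r >= -1 && r$pearson_r <= 1)
  expect_gte(r$rmse_mean, 0)
  expect_output(print(r), "Agreement report")
})
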