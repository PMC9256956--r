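#' Build a paired panel of observed and estimated core temperatures
#'
#' Joins minute-level observed Tc and estimated Tc by athlete and minute
#' into the panel all agreement statistics consume. The difference is
#' always `tc_est - tc` (estimate minus reference), so a positive bias
#' means the estimator reads high.
#'
#' @param aligned Data frame in the aligned layout
#'   (`athlete_id,minute,hr_bpm,tc_c,...`), see [aligned_table()].
#' @param estimates Data frame with `athlete_id`, `minute`, `tc_est_c`,
#'   see [estimates_table()].
#' @param groups Optional data frame `athlete_id,sex,discipline` carried
#'   as per-athlete labels.
#' @param drop_excluded Drop athletes whose aligned series carries a
#'   non-`none` exclusion flag (default `TRUE`; dropped ids are recorded
#'   in attribute `dropped`).
#' @return A `paired_panel`: data frame with `athlete_id`, `minute`, `tc`,
#'   `tc_est`, `diff` plus optional `sex`/`discipline`, rows with either
#'   temperature missing removed.
#' @export
paired_panel <- function(aligned, estimates, groups = NULL,
                         drop_excluded = TRUE) {
  dropped <- character(0)
  if (drop_excluded && "excluded" %in% names(aligned)) {
    dropped <- unique(aligned$athlete_id[aligned$excluded])
    aligned <- aligned[!aligned$athlete_id %in% dropped, , drop = FALSE]
  }
  m <- merge(aligned[, c("athlete_id", "minute", "tc_c")],
             estimates[, c("athlete_id", "minute", "tc_est_c")],
             by = c("athlete_id", "minute"))
  names(m)[names(m) == "tc_c"] <- "tc"
  names(m)[names(m) == "tc_est_c"] <- "tc_est"
  m <- m[is.finite(m$tc) & is.finite(m$tc_est), , drop = FALSE]
  if (nrow(m) == 0L) stopf("no paired observations after joining")
  m$diff <- m$tc_est - m$tc
  if (!is.null(groups))
    m <- merge(m, groups, by = "athlete_id", all.x = TRUE)
  m <- m[order(m$athlete_id, m$minute), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, dropped = dropped, class = c("paired_panel", "data.frame"))
}

#' Systematic bias and one-sample t-test
#'
#' Mean of the pooled differences (`tc_est - tc`) with a one-sample t-test
#' against zero. Pooled records are used, matching the conventional
#' Bland-Altman bias test; clustering by athlete is ignored here (see
#' [loa_repeated_measures()] for the clustered spread).
#'
#' @param panel A [paired_panel()].
#' @return List with `bias`, `sd_diff` (both °C), `t_stat`, `p_value`,
#'   `n`; `degenerate = TRUE` flags an all-identical nonzero difference,
#'   whose p-value underflows the machine floor.
#' @export
bias_and_ttest <- function(panel) {
  d <- panel$diff
  if (length(d) < 2L) stopf("need at least 2 records")
  s <- stats::sd(d)
  if (s == 0) {
    # zero spread: t is 0/0 (all-zero diffs) or infinite (constant offset)
    bias <- mean(d)
    return(list(bias = bias, sd_diff = 0,
                t_stat = if (bias == 0) 0 else sign(bias) * Inf,
                p_value = if (bias == 0) 1 else .Machine$double.xmin,
                n = length(d), degenerate = bias != 0))
  }
  tt <- stats::t.test(d, mu = 0)
  list(bias = mean(d), sd_diff = s, t_stat = unname(tt$statistic),
       p_value = tt$p.value, n = length(d), degenerate = FALSE)
}

#' Repeated-measures limits of agreement
#'
#' Half-width of the 95% limits of agreement for method-comparison data
#' with multiple, non-constant measurements per athlete. The pooled SD of
#' differences understates the spread when differences cluster within
#' athletes, so the total SD is rebuilt from a one-way random-effects
#' decomposition of the differences by athlete:
#' \deqn{\hat\sigma^2_b = \frac{MSB - MSW}{n_0},\qquad
#'       n_0 = \frac{N - \sum_i n_i^2 / N}{k - 1}}
#' (truncated at zero), with total SD
#' \eqn{\sqrt{\hat\sigma^2_b + MSW}} and half-width 1.96 times that.
#' With one record per athlete this reduces to the classic
#' 1.96 x SD of the differences, which is also the single-athlete
#' fallback (noted via attribute `note`).
#'
#' @param panel A [paired_panel()].
#' @return List with `loa_half_width`, `total_sd`, `msw`, `msb`,
#'   `between_var`, `n_athletes`, `n_obs`; attribute `note` when the
#'   fallback was used.
#' @export
loa_repeated_measures <- function(panel) {
  d <- panel$diff
  id <- panel$athlete_id
  k <- length(unique(id))
  N <- length(d)
  if (k < 2L) {
    out <- list(loa_half_width = 1.96 * stats::sd(d),
                total_sd = stats::sd(d), msw = NA_real_, msb = NA_real_,
                between_var = NA_real_, n_athletes = k, n_obs = N)
    attr(out, "note") <- "single athlete: classic 1.96*SD fallback"
    return(out)
  }
  ni <- tapply(d, id, length)
  mi <- tapply(d, id, mean)
  gm <- mean(d)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((d - mi[match(id, names(mi))])^2)
  msb <- ssb / (k - 1)
  if (N == k) {
    # one record per athlete: no within-athlete replication; the total SD
    # is just the SD of the per-athlete differences
    total_sd <- stats::sd(d)
    return(list(loa_half_width = 1.96 * total_sd, total_sd = total_sd,
                msw = 0, msb = msb, between_var = stats::var(d),
                n_athletes = k, n_obs = N))
  }
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  between_var <- max(0, (msb - msw) / n0)
  total_sd <- sqrt(between_var + msw)
  list(loa_half_width = 1.96 * total_sd, total_sd = total_sd, msw = msw,
       msb = msb, between_var = between_var, n_athletes = k, n_obs = N)
}

#' Pearson correlation between observed and estimated Tc
#'
#' Product-moment correlation over the pooled records.
#'
#' @param panel A [paired_panel()].
#' @return The correlation coefficient.
#' @export
pearson <- function(panel) {
  if (nrow(panel) < 3L) stopf("need at least 3 records")
  if (stats::sd(panel$tc) == 0 || stats::sd(panel$tc_est) == 0)
    stopf("correlation undefined: zero variance in one variable")
  stats::cor(panel$tc, panel$tc_est)
}

#' Participant- and duration-weighted RMSE
#'
#' Per-athlete RMSE of the differences, aggregated with weights equal to
#' each athlete's number of retained minutes (the test duration), so long
#' tests count proportionally more:
#' \deqn{RMSE_i = \sqrt{\tfrac1{n_i}\sum_t d_{it}^2},\qquad
#'   \overline{RMSE} = \frac{\sum_i n_i RMSE_i}{\sum_i n_i}}
#' The spread is the weighted SD of the per-athlete RMSEs under the same
#' weights (denominator \eqn{\sum n_i}).
#'
#' @param panel A [paired_panel()].
#' @return List with `rmse_mean`, `rmse_sd` (°C) and `per_athlete`, a named
#'   vector of per-athlete RMSEs.
#' @export
weighted_rmse <- function(panel) {
  ni <- tapply(panel$diff, panel$athlete_id, length)
  rmse_i <- sqrt(tapply(panel$diff^2, panel$athlete_id, mean))
  w <- ni / sum(ni)
  m <- sum(w * rmse_i)
  list(rmse_mean = m, rmse_sd = sqrt(sum(w * (rmse_i - m)^2)),
       per_athlete = rmse_i)
}

#' One record per athlete: the peak panel
#'
#' Reduces a paired panel to one record per athlete, pairing the maximum
#' observed Tc with the maximum estimated Tc. The maxima are taken
#' independently per series — the estimated peak need not fall in the same
#' minute as the observed peak — which matches how peak values are read
#' off monitoring traces in practice.
#'
#' @param panel A [paired_panel()] (all-data).
#' @return A `paired_panel` with exactly one record per athlete; `minute`
#'   is the minute of the observed peak.
#' @export
peak_panel <- function(panel) {
  sp <- split(seq_len(nrow(panel)), panel$athlete_id)
  rows <- lapply(sp, function(ix) {
    sub <- panel[ix, , drop = FALSE]
    i_tc <- which.max(sub$tc)
    out <- sub[i_tc, , drop = FALSE]
    out$tc_est <- max(sub$tc_est)
    out$diff <- out$tc_est - out$tc
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, dropped = attr(panel, "dropped"),
            class = c("paired_panel", "data.frame"))
}

#' Subgroup comparison of per-athlete RMSE
#'
#' One-way ANOVA of the per-athlete RMSEs across a grouping (sex, or sport
#' discipline). Groups with fewer than 2 members are excluded with a
#' notice.
#'
#' @param per_athlete_rmse Named numeric vector of per-athlete RMSEs (as
#'   from [weighted_rmse()]`$per_athlete`).
#' @param labels Named character vector mapping athlete id to group label.
#' @return List with `F`, `p_value`, `df`, `groups_used`,
#'   `excluded_groups`.
#' @export
subgroup_anova <- function(per_athlete_rmse, labels) {
  g <- labels[names(per_athlete_rmse)]
  if (any(is.na(g))) stopf("missing group label for some athletes")
  tab <- table(g)
  small <- names(tab)[tab < 2]
  keep <- !(g %in% small)
  if (length(small) > 0)
    message("subgroup_anova: excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
  g <- factor(g[keep])
  y <- per_athlete_rmse[keep]
  if (nlevels(g) < 2L) stopf("need at least 2 groups with >= 2 members")
  if (stats::var(y) == 0)
    # no variation at all: no between-group signal by construction
    return(list(F = 0, p_value = 1,
                df = c(nlevels(g) - 1L, length(y) - nlevels(g)),
                groups_used = levels(g), excluded_groups = small))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       df = s[["Df"]], groups_used = levels(g), excluded_groups = small)
}

#' Full agreement report
#'
#' Bias with t-test, pooled and repeated-measures spread, Pearson
#' correlation and weighted RMSE, for a panel of paired observations.
#'
#' @param panel A [paired_panel()].
#' @param scope Label stored in the report, e.g. `"all_data"` or
#'   `"peak_data"`.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(panel, scope = "all_data") {
  b <- bias_and_ttest(panel)
  l <- loa_repeated_measures(panel)
  r <- weighted_rmse(panel)
  out <- list(scope = scope, bias = b$bias, sd_diff = b$sd_diff,
              t_stat = b$t_stat, p_value = b$p_value,
              loa_half_width = l$loa_half_width, total_sd = l$total_sd,
              pearson_r = pearson(panel), rmse_mean = r$rmse_mean,
              rmse_sd = r$rmse_sd, n_obs = nrow(panel),
              n_athletes = length(unique(panel$athlete_id)))
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s): %d obs from %d athletes\n",
              x$scope, x$n_obs, x$n_athletes))
  cat(sprintf("  bias %+.3f degC (pooled SD %.3f, p = %.3g)\n",
              x$bias, x$sd_diff, x$p_value))
  cat(sprintf("  repeated-measures LoA half-width %.3f degC (total SD %.3f)\n",
              x$loa_half_width, x$total_sd))
  cat(sprintf("  Pearson r = %.3f; weighted RMSE %.3f +/- %.3f degC\n",
              x$pearson_r, x$rmse_mean, x$rmse_sd))
  invisible(x)
}
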