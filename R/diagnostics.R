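#' Confusion table at one exceedance threshold
#'
#' Treats the estimator as a diagnostic test for "core temperature has
#' exceeded `threshold`": a record is actually positive iff `tc >
#' threshold` and predicted positive iff `tc_est > threshold` (strict
#' inequality on both sides).
#'
#' @param panel A [paired_panel()].
#' @param threshold Exceedance threshold in °C.
#' @return A `confusion_table` list: `threshold`, counts `tp`, `fp`, `tn`,
#'   `fn`, unrounded percents `accuracy`, `sensitivity`, `specificity`
#'   (`NA` when the denominator is zero) and their half-up-rounded integer
#'   forms `accuracy_pct`, `sensitivity_pct`, `specificity_pct`.
#' @examples
#' p <- structure(data.frame(athlete_id = "a", minute = 0:2,
#'                           tc = c(38.6, 38.8, 39.1),
#'                           tc_est = c(38.7, 38.7, 38.9)),
#'                class = c("paired_panel", "data.frame"))
#' p$diff <- p$tc_est - p$tc
#' confusion_at_threshold(p, 38.75)[c("tp", "fp", "tn", "fn")]
#' @export
confusion_at_threshold <- function(panel, threshold) {
  if (nrow(panel) == 0L) stopf("panel is empty")
  actual <- panel$tc > threshold
  pred <- panel$tc_est > threshold
  counts <- c(tp = sum(actual & pred), fp = sum(!actual & pred),
              tn = sum(!actual & !pred), fn = sum(actual & !pred))
  c(list(threshold = threshold), as.list(counts),
    metrics_from_counts(counts[["tp"]], counts[["fp"]], counts[["tn"]],
                        counts[["fn"]])) |>
    structure(class = "confusion_table")
}

#' Accuracy, sensitivity and specificity from counts
#'
#' Exact rational computation from confusion counts, with the reporting
#' convention used for published classification tables: percentages
#' rounded half-up to integers. A metric whose denominator is zero is
#' `NA` (not applicable), never 0 or 100.
#'
#' @param tp,fp,tn,fn Non-negative counts; their sum must be positive.
#' @return List with unrounded `accuracy`, `sensitivity`, `specificity`
#'   (percent) and rounded `accuracy_pct`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @examples
#' metrics_from_counts(456, 313, 4090, 166)  # sens 73, spec 93, acc 90
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stopf("counts sum to zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- ratio(tp + tn, total)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       accuracy_pct = round_half_up(acc),
       sensitivity_pct = round_half_up(sens),
       specificity_pct = round_half_up(spec))
}

#' Sweep a threshold grid
#'
#' One confusion table per threshold. The default all-data grid runs from
#' 37.00 to 39.75 °C in 0.25 °C steps (12 thresholds); for
#' `scope = "peak_data"` the default grid is 39.00-39.75 °C (4
#' thresholds), the range where peak exceedance matters.
#'
#' @param panel A [paired_panel()].
#' @param grid Increasing numeric vector of thresholds (°C); defaulted
#'   from `scope`.
#' @param scope `"all_data"` or `"peak_data"`; sets the default grid and
#'   is recorded in the result.
#' @return A `threshold_sweep` data frame with one row per threshold:
#'   `scope`, `threshold_c`, counts, unrounded and rounded metrics, and
#'   grades for sensitivity and specificity.
#' @export
threshold_sweep <- function(panel, grid = NULL,
                            scope = c("all_data", "peak_data")) {
  scope <- match.arg(scope)
  grid <- grid %||% if (scope == "all_data") seq(37.0, 39.75, by = 0.25)
  else seq(39.0, 39.75, by = 0.25)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stopf("grid must be non-empty and strictly increasing")
  rows <- lapply(grid, function(th) {
    ct <- confusion_at_threshold(panel, th)
    data.frame(scope = scope, threshold_c = th, tp = ct$tp, fp = ct$fp,
               tn = ct$tn, fn = ct$fn,
               accuracy = ct$accuracy, sensitivity = ct$sensitivity,
               specificity = ct$specificity,
               accuracy_pct = ct$accuracy_pct,
               sensitivity_pct = ct$sensitivity_pct,
               specificity_pct = ct$specificity_pct,
               sens_grade = grade(ct$sensitivity_pct),
               spec_grade = grade(ct$specificity_pct))
  })
  structure(do.call(rbind, rows), class = c("threshold_sweep", "data.frame"))
}

#' Qualitative grade of a diagnostic percentage
#'
#' Bands applied to the rounded integer percent: 90-100 excellent, 80-89
#' good, 70-79 fair, 60-69 poor, below 60 failure. `NA` input (a metric
#' with zero denominator) grades as `NA`.
#'
#' @param metric_value Percent value(s) in `[0, 100]`, or `NA`.
#' @return Character vector of grades.
#' @examples
#' grade(c(73, 90, 59))
#' @export
grade <- function(metric_value) {
  vapply(metric_value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0 || v > 100) stopf("metric value %g outside [0, 100]", v)
    v <- round_half_up(v)
    if (v >= 90) "excellent"
    else if (v >= 80) "good"
    else if (v >= 70) "fair"
    else if (v >= 60) "poor"
    else "failure"
  }, character(1))
}

#' Path to the published validation counts
#'
#' The package ships, as a plain-text fixture, the confusion counts of a
#' published validation of this estimator in elite athletes (5,025 paired
#' minute observations, 12 exceedance thresholds from 37.0 to 39.75 °C),
#' together with the metric percentages as printed. Used by
#' [check_published_counts()] to confirm that the metric formulas and
#' rounding convention reproduce every printed cell.
#'
#' @return Path to `published_confusion_counts.csv`.
#' @export
published_counts_path <- function() {
  system.file("extdata", "published_confusion_counts.csv",
              package = "coretemp", mustWork = TRUE)
}

#' Recompute published classification metrics from their counts
#'
#' Reads a table of published confusion counts (columns `threshold_c`,
#' `tp`, `fp`, `tn`, `fn`, `accuracy_pct`, `sensitivity_pct`,
#' `specificity_pct`) and recomputes accuracy, sensitivity and specificity
#' from the raw counts, comparing against the printed percentages. A
#' mismatch larger than `tol` percentage points (default 1, absorbing the
#' unknown rounding convention of the source) is reported; column count
#' sums are checked against `expected_total` when given.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @param tol Allowed |recomputed - printed| in percentage points.
#' @param expected_total Expected per-threshold count total
#'   (default 5025, the packaged fixture's total), or `NULL` to skip.
#' @return List with `table` (counts plus recomputed metrics and printed
#'   ones), `mismatches` (rows × metrics beyond `tol`), `sum_ok` (logical
#'   per threshold) and `ok` (overall).
#' @export
check_published_counts <- function(path = published_counts_path(),
                                   tol = 1, expected_total = 5025) {
  tab <- utils::read.csv(path)
  need <- c("threshold_c", "tp", "fp", "tn", "fn", "accuracy_pct",
            "sensitivity_pct", "specificity_pct")
  if (!all(need %in% names(tab)))
    stopf("malformed fixture: missing column(s) %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  rec <- lapply(seq_len(nrow(tab)), function(i)
    metrics_from_counts(tab$tp[i], tab$fp[i], tab$tn[i], tab$fn[i]))
  tab$accuracy_recomputed <- vapply(rec, `[[`, numeric(1), "accuracy")
  tab$sensitivity_recomputed <- vapply(rec, `[[`, numeric(1), "sensitivity")
  tab$specificity_recomputed <- vapply(rec, `[[`, numeric(1), "specificity")

  mism <- data.frame(threshold_c = numeric(0), metric = character(0),
                     printed = numeric(0), recomputed = numeric(0))
  for (metric in c("accuracy", "sensitivity", "specificity")) {
    printed <- tab[[paste0(metric, "_pct")]]
    recomputed <- tab[[paste0(metric, "_recomputed")]]
    bad <- which(abs(recomputed - printed) > tol)
    if (length(bad))
      mism <- rbind(mism, data.frame(threshold_c = tab$threshold_c[bad],
                                     metric = metric,
                                     printed = printed[bad],
                                     recomputed = recomputed[bad]))
  }
  sums <- tab$tp + tab$fp + tab$tn + tab$fn
  sum_ok <- if (is.null(expected_total)) rep(TRUE, nrow(tab))
  else sums == expected_total
  list(table = tab, mismatches = mism, sum_ok = sum_ok,
       ok = nrow(mism) == 0L && all(sum_ok))
}
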