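.pair_diffs <- function(pairs, target = c("SBP", "DBP")) {
  target <- match.arg(target)
  if (target == "SBP") pairs$test_sbp - pairs$ref_sbp
  else pairs$test_dbp - pairs$ref_dbp
}

#' Mean and SD of test-minus-reference differences
#'
#' @param pairs Comparison-pair data frame from [build_pairs()].
#' @param target `"SBP"` or `"DBP"`.
#' @return List with `mean_diff`, `sd_diff` (sample SD, N-1 denominator),
#'   and `n`.
#' @export
diff_stats <- function(pairs, target = c("SBP", "DBP")) {
  d <- .pair_diffs(pairs, target)
  if (length(d) < 2L) stop("need at least 2 pairs", call. = FALSE)
  list(mean_diff = mean(d), sd_diff = stats::sd(d), n = length(d))
}

#' ISO 81060-2 criterion 1
#'
#' Pass iff `|mean_diff| <= 5` mmHg and `sd_diff <= 8.0` mmHg, both
#' inclusive.
#'
#' @param mean_diff,sd_diff Pooled mean and SD of the test-minus-reference
#'   differences, mmHg.
#' @return Logical.
#' @export
iso_criterion1 <- function(mean_diff, sd_diff) {
  stopifnot(is.finite(mean_diff), is.finite(sd_diff))
  abs(mean_diff) <= 5 && sd_diff <= 8.0
}

#' SD of per-subject mean differences (criterion-2 statistic)
#'
#' Computes each subject's mean test-minus-reference difference first,
#' then the sample SD (N-1) across subject means.
#'
#' @inheritParams diff_stats
#' @return SD across subject means, mmHg.
#' @export
per_subject_sd <- function(pairs, target = c("SBP", "DBP")) {
  d <- .pair_diffs(pairs, target)
  means <- tapply(d, pairs$subject_id, mean)
  if (length(means) < 2L) stop("need at least 2 subjects", call. = FALSE)
  stats::sd(means)
}

#' ISO 81060-2 criterion 2
#'
#' Pass iff the SD of per-subject mean differences is at most 6.89 mmHg
#' for SBP or 6.84 mmHg for DBP (inclusive).
#'
#' @param sd_value SD of per-subject mean differences, mmHg.
#' @param target `"SBP"` or `"DBP"`.
#' @return Logical.
#' @export
iso_criterion2 <- function(sd_value, target = c("SBP", "DBP")) {
  target <- match.arg(target)
  stopifnot(is.finite(sd_value))
  sd_value <= c(SBP = 6.89, DBP = 6.84)[[target]]
}

#' Cumulative percentages of absolute differences
#'
#' Percentage of absolute differences within 5, 10, and 15 mmHg
#' (inclusive).
#'
#' @param diffs Numeric vector of test-minus-reference differences, mmHg.
#' @return Named numeric vector `c(le5, le10, le15)` of percentages.
#' @export
#' @examples
#' cumulative_pct(c(3, -7, 12))
cumulative_pct <- function(diffs) {
  if (length(diffs) == 0L) stop("empty differences", call. = FALSE)
  a <- abs(diffs)
  c(le5 = 100 * mean(a <= 5), le10 = 100 * mean(a <= 10),
    le15 = 100 * mean(a <= 15))
}

.bhs_thresholds <- rbind(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' British Hypertension Society grade
#'
#' The grade is the best of A/B/C whose three cumulative-percentage
#' thresholds are *all* met; D otherwise. Grade A requires at least 60%,
#' 85%, and 95% of absolute differences within 5, 10, and 15 mmHg;
#' B requires 50/75/90; C requires 40/65/85.
#'
#' @param cum_pct Numeric triple of cumulative percentages at 5/10/15 mmHg
#'   (as from [cumulative_pct()]).
#' @return `"A"`, `"B"`, `"C"`, or `"D"`.
#' @export
bhs_grade <- function(cum_pct) {
  cp <- as.numeric(cum_pct)
  stopifnot(length(cp) == 3L, all(is.finite(cp)), all(cp >= 0), all(cp <= 100))
  for (g in rownames(.bhs_thresholds)) {
    if (all(cp >= .bhs_thresholds[g, ])) return(g)
  }
  "D"
}

#' Bland-Altman analysis
#'
#' Mean difference and limits of agreement (mean +/- 1.96 SD).
#'
#' @param pairs Comparison-pair data frame, or a numeric vector of
#'   differences.
#' @param target `"SBP"` or `"DBP"` (ignored when `pairs` is numeric).
#' @return List with `mean`, `lower_loa`, `upper_loa` (mmHg) and `n`.
#' @export
bland_altman <- function(pairs, target = c("SBP", "DBP")) {
  d <- if (is.numeric(pairs)) pairs else .pair_diffs(pairs, target)
  if (length(d) < 3L) stop("need at least 3 pairs", call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  list(mean = m, lower_loa = m - 1.96 * s, upper_loa = m + 1.96 * s,
       n = length(d))
}

#' Pearson correlation between test and reference readings
#'
#' @param test,reference Numeric vectors of equal length (>= 3), each with
#'   nonzero variance.
#' @return List with `r` and the two-sided t-distribution `p` value.
#' @export
pearson_r <- function(test, reference) {
  if (length(test) != length(reference) || length(test) < 3L) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(test) == 0 || stats::sd(reference) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(test, reference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

.one_report <- function(pairs, week, target) {
  d <- .pair_diffs(pairs, target)
  ds <- diff_stats(pairs, target)
  ps_sd <- if (length(unique(pairs$subject_id)) >= 2L) {
    per_subject_sd(pairs, target)
  } else {
    NA_real_
  }
  cp <- cumulative_pct(d)
  ba <- bland_altman(d)
  tv <- if (target == "SBP") pairs$test_sbp else pairs$test_dbp
  rv <- if (target == "SBP") pairs$ref_sbp else pairs$ref_dbp
  pr <- if (stats::sd(tv) > 0 && stats::sd(rv) > 0) pearson_r(tv, rv) else
    list(r = NA_real_, p = NA_real_)
  data.frame(
    week = week, target = target, n_pairs = ds$n,
    mean_diff = ds$mean_diff, sd_diff = ds$sd_diff,
    per_subject_sd = ps_sd,
    pct_le5 = cp[["le5"]], pct_le10 = cp[["le10"]], pct_le15 = cp[["le15"]],
    iso1_pass = iso_criterion1(ds$mean_diff, ds$sd_diff),
    iso2_pass = if (is.na(ps_sd)) NA else iso_criterion2(ps_sd, target),
    bhs_grade = bhs_grade(cp),
    ba_mean = ba$mean, ba_lower = ba$lower_loa, ba_upper = ba$upper_loa,
    pearson_r = pr$r, pearson_p = pr$p,
    stringsAsFactors = FALSE)
}

#' Weekly validation report
#'
#' Assembles, per week and target, every accuracy statistic: pooled mean
#' and SD of differences, per-subject SD, cumulative percentages within
#' 5/10/15 mmHg, ISO 81060-2 criterion 1 and 2 pass flags, BHS grade,
#' Bland-Altman limits, and Pearson correlation.
#'
#' @param pairs Comparison-pair data frame labeled by `week`.
#' @param weeks Weeks to report (default 1:5); weeks absent from `pairs`
#'   are omitted with a warning.
#' @return Data frame of class `bp_validation_report`, one row per
#'   week x target.
#' @export
weekly_report <- function(pairs, weeks = 1:5) {
  present <- intersect(weeks, unique(pairs$week))
  missing <- setdiff(weeks, present)
  if (length(missing)) {
    warning("no pairs for week(s) ", paste(missing, collapse = ", "),
            "; report omitted", call. = FALSE)
  }
  reports <- list()
  for (w in present) {
    pw <- pairs[pairs$week == w, ]
    for (tg in c("SBP", "DBP")) {
      reports[[length(reports) + 1L]] <- .one_report(pw, w, tg)
    }
  }
  if (length(reports) == 0L) stop("no weeks to report", call. = FALSE)
  structure(do.call(rbind, reports),
            class = c("bp_validation_report", "data.frame"))
}

#' @export
print.bp_validation_report <- function(x, ...) {
  cat("Blood-pressure validation report (test - reference, mmHg)\n")
  df <- data.frame(
    week = x$week, target = x$target, n = x$n_pairs,
    `mean+/-SD` = sprintf("%.2f +/- %.2f", x$mean_diff, x$sd_diff),
    `<=5` = sprintf("%.1f%%", x$pct_le5),
    `<=10` = sprintf("%.1f%%", x$pct_le10),
    `<=15` = sprintf("%.1f%%", x$pct_le15),
    BHS = x$bhs_grade,
    ISO1 = ifelse(x$iso1_pass, "pass", "FAIL"),
    ISO2 = ifelse(is.na(x$iso2_pass), "-", ifelse(x$iso2_pass, "pass", "FAIL")),
    r = sprintf("%.3f", x$pearson_r),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
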