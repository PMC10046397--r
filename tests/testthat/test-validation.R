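# Minimal pair table from explicit difference vectors (reference held flat).
pairs_from_diffs <- function(diffs, subject_id = paste0("s", seq_along(diffs)),
                             week = 1) {
  data.frame(subject_id = subject_id, week = week,
             ref_slot = "BP3", ref_sbp = 120, ref_dbp = 80,
             test_sbp = 120 + diffs, test_dbp = 80 + diffs)
}

test_that("difference statistics use the sample (N-1) definition", {
  expect_equal(diff_stats(pairs_from_diffs(c(0, 0, 0)), "SBP"),
               list(mean_diff = 0, sd_diff = 0, n = 3L))
  ds <- diff_stats(pairs_from_diffs(c(-1, 0, 1)), "SBP")
  expect_equal(ds$mean_diff, 0)
  expect_equal(ds$sd_diff, 1)
  ds5 <- diff_stats(pairs_from_diffs(rep(5, 4)), "DBP")
  expect_equal(ds5$mean_diff, 5)
  expect_equal(ds5$sd_diff, 0)
  expect_error(diff_stats(pairs_from_diffs(1)), "at least 2")

  # two-pass streaming oracle agreement on random data
  set.seed(41)
  d <- rnorm(200, 1, 4)
  ds <- diff_stats(pairs_from_diffs(d), "SBP")
  expect_equal(ds$mean_diff, sum(d) / 200, tolerance = 1e-12)
  expect_equal(ds$sd_diff, sqrt(sum((d - mean(d))^2) / 199), tolerance = 1e-12)
})

test_that("ISO criterion 1 is inclusive at its boundaries", {
  expect_true(iso_criterion1(-1.86, 5.50))  # week-1 diastolic published pair
  expect_true(iso_criterion1(-5.0, 8.0))
  expect_false(iso_criterion1(5.1, 7.0))
  expect_false(iso_criterion1(0, 8.01))
})

test_that("per-subject SD averages within subject first", {
  p <- rbind(pairs_from_diffs(c(-1, -1), subject_id = "a"),
             pairs_from_diffs(c(1, 1), subject_id = "b"))
  expect_equal(per_subject_sd(p, "SBP"), sqrt(2))
  p2 <- rbind(pairs_from_diffs(c(2, 2, 2), subject_id = "a"),
              pairs_from_diffs(c(2, 2), subject_id = "b"))
  expect_equal(per_subject_sd(p2, "SBP"), 0)
  # one pair per subject degenerates to the pooled SD
  d <- c(-3, 0, 2, 5)
  p3 <- pairs_from_diffs(d)
  expect_equal(per_subject_sd(p3, "SBP"), sd(d))
  expect_error(per_subject_sd(pairs_from_diffs(c(1, 2), subject_id = "a")),
               "at least 2 subjects")
})

test_that("ISO criterion 2 applies the per-target inclusive bounds", {
  expect_true(iso_criterion2(6.82, "SBP"))   # published week-1 systolic value
  expect_true(iso_criterion2(6.89, "SBP"))
  expect_false(iso_criterion2(6.90, "SBP"))
  expect_true(iso_criterion2(6.62, "DBP"))
  expect_true(iso_criterion2(6.84, "DBP"))
  expect_false(iso_criterion2(6.85, "DBP"))
})

test_that("cumulative percentages count absolute differences inclusively", {
  expect_equal(cumulative_pct(c(3, -7, 12)),
               c(le5 = 100 / 3, le10 = 200 / 3, le15 = 100))
  expect_equal(cumulative_pct(rep(0, 5)), c(le5 = 100, le10 = 100, le15 = 100))
  # boundary values count inclusively at their own threshold
  expect_equal(cumulative_pct(c(5, 10, 15)),
               c(le5 = 100 / 3, le10 = 200 / 3, le15 = 100))
  expect_error(cumulative_pct(numeric(0)), "empty")
  set.seed(42)
  for (i in 1:10) {
    cp <- cumulative_pct(rnorm(50, 0, 8))
    expect_true(all(diff(cp) >= 0))
  }
})

test_that("BHS grading requires all three thresholds of a grade", {
  expect_equal(bhs_grade(c(60, 85, 95)), "A")
  expect_equal(bhs_grade(c(59, 85, 95)), "B")
  expect_equal(bhs_grade(c(57.29, 92.71, 98.96)), "B")
  expect_equal(bhs_grade(c(50, 75, 90)), "B")
  expect_equal(bhs_grade(c(40, 65, 85)), "C")
  expect_equal(bhs_grade(c(39, 95, 99)), "D")
  expect_equal(bhs_grade(c(0, 0, 0)), "D")
  # monotonicity: improving any percentage never worsens the grade
  set.seed(43)
  grades <- c(D = 0, C = 1, B = 2, A = 3)
  for (i in 1:50) {
    cp <- sort(runif(3, 0, 100))
    j <- sample(1:3, 1)
    cp2 <- cp; cp2[j] <- min(100, cp2[j] + runif(1, 0, 30))
    expect_gte(grades[[bhs_grade(cp2)]], grades[[bhs_grade(cp)]])
  }
})

test_that("Bland-Altman limits are mean +/- 1.96 SD", {
  ba <- bland_altman(c(-1, 0, 1))
  expect_equal(ba$mean, 0)
  expect_equal(ba$lower_loa, -1.96)
  expect_equal(ba$upper_loa, 1.96)
  ba0 <- bland_altman(pairs_from_diffs(rep(0, 4)), "SBP")
  expect_equal(c(ba0$mean, ba0$lower_loa, ba0$upper_loa), c(0, 0, 0))
  set.seed(44)
  for (i in 1:5) {
    ba <- bland_altman(rnorm(30, 2, 5))
    expect_lt(ba$lower_loa, ba$mean)
    expect_gt(ba$upper_loa, ba$mean)
  }
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("Pearson correlation matches the covariance formula", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(0.9, 2.8, 2.9, 4.2, 4.4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_hand, tolerance = 1e-12)
  expect_lt(pearson_r(x, y)$p, 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

test_that("weekly reports assemble all statistics and warn on gaps", {
  set.seed(45)
  pairs <- do.call(rbind, lapply(1:3, function(wk) {
    pairs_from_diffs(rnorm(30, -1, 4), subject_id = rep(paste0("s", 1:10), 3),
                     week = wk)
  }))
  expect_warning(rep5 <- weekly_report(pairs, weeks = 1:5), "week")
  expect_equal(nrow(rep5), 6)  # 3 weeks x 2 targets
  expect_true(all(rep5$pct_le5 <= rep5$pct_le10))
  expect_true(all(rep5$pct_le10 <= rep5$pct_le15))
  expect_true(all(c("mean_diff", "sd_diff", "per_subject_sd", "bhs_grade",
                    "iso1_pass", "iso2_pass", "ba_lower", "pearson_r")
                  %in% names(rep5)))

  # statistics are invariant under pair reordering
  shuffled <- pairs[sample(nrow(pairs)), ]
  rep_a <- weekly_report(pairs, weeks = 1:3)
  rep_b <- weekly_report(shuffled, weeks = 1:3)
  expect_equal(rep_a$mean_diff, rep_b$mean_diff, tolerance = 1e-12)
  expect_equal(rep_a$sd_diff, rep_b$sd_diff, tolerance = 1e-12)
  expect_equal(rep_a$per_subject_sd, rep_b$per_subject_sd, tolerance = 1e-12)
})
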