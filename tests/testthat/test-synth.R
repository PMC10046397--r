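test_that("profile and morphology inputs are validated", {
  expect_error(subject_profile("s", 210, 80), "sbp_true")
  expect_error(subject_profile("s", 120, 130), "dbp_true")
  expect_error(subject_profile("s", 80, 80), "exceed")
  expect_error(subject_profile("s", 120, 80, heart_rate = 30), "heart_rate")
  expect_error(bp_to_morphology(50, 40), "outside supported range")
  expect_error(bp_to_morphology(120, 130), "dbp")
  expect_error(synth_pulse(subject_profile("s", 120, 80), quality = "superb"),
               "unknown quality tier")
})

test_that("morphology mapping is deterministic, monotone, and injective", {
  m1 <- bp_to_morphology(120, 80)
  expect_identical(m1, bp_to_morphology(120, 80))
  # systolic time strictly decreases with SBP
  expect_lt(bp_to_morphology(121, 80)$sys_center_frac, m1$sys_center_frac)
  # diastolic-to-systolic amplitude (hence area) ratio strictly increases
  # with DBP
  expect_gt(bp_to_morphology(120, 81)$amp_dia_ratio, m1$amp_dia_ratio)
  # injectivity over a 50-point BP grid: no two parameter vectors coincide
  grid <- expand.grid(sbp = seq(100, 180, by = 10), dbp = seq(50, 95, by = 5))
  grid <- grid[grid$sbp > grid$dbp + 20, ][1:50, ]
  pars <- t(apply(grid, 1, function(r) unlist(bp_to_morphology(r[1], r[2]))))
  expect_equal(nrow(unique(as.data.frame(pars))), 50)
})

test_that("single beats are deterministic with the expected peak location", {
  p <- subject_profile("s", 120, 80, heart_rate = 60)
  b1 <- synth_pulse(p, "excellent", rng_seed = 7)
  b2 <- synth_pulse(p, "excellent", rng_seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_length(b1, round(256 * 60 / 60))

  # closed-form oracle: with well-separated lobes the beat maximum sits at
  # the systolic-lobe center (the diastolic tail contributes ~exp(-8) there)
  m <- bp_to_morphology(120, 80)
  center_sample <- round(m$sys_center_frac * (60 / 60) * 256) + 1
  expect_lte(abs(which.max(b1) - center_sample), 1)
})

test_that("a zero-amplitude morphology yields a flat beat", {
  p <- subject_profile("s", 120, 80, heart_rate = 60)
  m <- bp_to_morphology(120, 80)
  m$amp_sys <- 0
  b <- synth_pulse(p, "excellent", rng_seed = 1, morph = m)
  expect_true(all(b == attr(b, "noise")))
  expect_true(all(abs(b) < 1e-12))  # zero signal power -> zero scaled noise
})

test_that("quality tiers are ordered by realized SNR", {
  p <- subject_profile("s", 130, 85, heart_rate = 72)
  snr_of <- function(tier) {
    mean(vapply(1:100, function(s) {
      b <- synth_pulse(p, tier, rng_seed = s)
      10 * log10(mean(attr(b, "clean")^2) / mean(attr(b, "noise")^2))
    }, numeric(1)))
  }
  s <- vapply(c("fair", "good", "excellent"), snr_of, numeric(1))
  expect_lt(s[["fair"]], s[["good"]])
  expect_lt(s[["good"]], s[["excellent"]])
})

test_that("recordings carry the expected beats, baseline, and truth", {
  p <- subject_profile("s", 120, 80, heart_rate = 60, resp_rate = 15)
  rec <- synth_recording(p, 15, "excellent", rng_seed = 3)
  expect_s3_class(rec, "ppg_record")
  expect_length(rec$samples, round(256 * 15))
  expect_true(abs(length(rec$onsets) - 15) <= 1)

  # identical inputs give bit-identical records
  rec2 <- synth_recording(p, 15, "excellent", rng_seed = 3)
  expect_identical(rec$samples, rec2$samples)

  # zero respiration and no noise -> DC component deviates from a constant
  # only through filter leakage of the cardiac band
  p0 <- subject_profile("s", 120, 80, heart_rate = 60, resp_rate = 0)
  rec0 <- synth_recording(p0, 15, "excellent", rng_seed = 3, noise = FALSE)
  dc0 <- rec0$samples - attr(rec0, "ac_clean")
  expect_lt(diff(range(dc0)), 1e-9 * mean(dc0))

  # 60-s recording -> four 15-s truth windows
  rec60 <- synth_recording(p, 60, "excellent", rng_seed = 3)
  expect_equal(nrow(rec60$truth), 4)
  expect_error(synth_recording(p, 0.5), "at least one beat")
})

test_that("features of noiseless windows invert to BP via nearest neighbour", {
  # dense BP grid -> features; queries at grid midpoints must recover the
  # true pressures to within the grid half-spacing (1 mmHg)
  hr <- 70
  grid <- expand.grid(sbp = seq(110, 130, by = 2), dbp = seq(70, 84, by = 2))
  feat_of <- function(sbp, dbp) {
    rec <- synth_recording(subject_profile("g", sbp, dbp, heart_rate = hr),
                           10, "excellent", rng_seed = 1, noise = FALSE)
    ac <- acdc_split(rec)$ac
    as.numeric(extract_features(
      lapply(segment_pulses(ac, rec$fs), detect_peaks), rec$fs))
  }
  Xg <- t(mapply(feat_of, grid$sbp, grid$dbp))
  ctr <- colMeans(Xg); scl <- apply(Xg, 2, sd)
  # drop columns that are constant on the fixed-heart-rate grid (e.g. the
  # peak-to-peak interval) up to landmark quantization: standardizing them
  # would amplify pure quantization noise
  keep <- scl > 1e-6 + 1e-3 * apply(abs(Xg), 2, stats::median)
  Xgs <- sweep(sweep(Xg[, keep], 2, ctr[keep], "-"), 2, scl[keep], "/")

  set.seed(11)
  queries <- data.frame(sbp = sample(seq(111, 129, by = 2), 8, TRUE),
                        dbp = sample(seq(71, 83, by = 2), 8, TRUE))
  for (q in seq_len(nrow(queries))) {
    fq <- (feat_of(queries$sbp[q], queries$dbp[q])[keep] - ctr[keep]) /
      scl[keep]
    nn <- which.min(rowSums(sweep(Xgs, 2, fq, "-")^2))
    expect_lte(abs(grid$sbp[nn] - queries$sbp[q]), 1)
    expect_lte(abs(grid$dbp[nn] - queries$dbp[q]), 1)
  }
})
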