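#' Default pipeline configuration
#'
#' The run configuration for the end-to-end simulated validation study.
#' Signal parameters: 256 Hz sampling, 15-s feature windows, 0.5 Hz DC
#' cutoff, 5% diastolic prominence, 12 dB excellent-SNR threshold.
#' Model constants: kernel scale 11.9 and signal SD 9.6, held fixed
#' during fine-tuning. Study design: a pretraining cohort (wrist
#' surrogate), a fine-tuning cohort (upper arm), and a 30-subject
#' validation cohort followed over 5 weekly sessions with a single
#' week-1 cuff calibration.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list of class `ppgbp_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    fs = 256, window_s = 15, dc_cutoff = 0.5,
    dia_prominence = 0.05, snr_excellent_db = 12,
    kernel_scale = 11.9, signal_std = 9.6,
    n_subjects = 30, n_weeks = 5,
    pretrain_subjects = 35, finetune_subjects = 25, train_duration = 60,
    estimate_duration = 15, quality = "excellent",
    observer_sd = 1.5, slot_bp_sd = 1, weekly_drift_sd = 2,
    sbp_range = c(95, 165), dbp_range = c(60, 100), min_pulse_pressure = 25,
    hr_range = c(55, 95), resp_range = c(12, 18),
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  numeric_pos <- c("fs", "window_s", "dc_cutoff", "kernel_scale", "signal_std")
  stopifnot(all(unlist(cfg[numeric_pos]) > 0))
  structure(cfg, class = c("ppgbp_config", "list"))
}

# Draw a cohort of subject profiles with BP spread across the supported
# normotensive-to-hypertensive range (caller must hold the RNG seed).
.draw_cohort <- function(n, cfg, prefix) {
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      sbp <- stats::runif(1, cfg$sbp_range[1], cfg$sbp_range[2])
      dbp <- stats::runif(1, cfg$dbp_range[1], cfg$dbp_range[2])
      if (sbp - dbp >= cfg$min_pulse_pressure) break
    }
    profs[[i]] <- subject_profile(
      sprintf("%s%02d", prefix, i), sbp, dbp,
      heart_rate = stats::runif(1, cfg$hr_range[1], cfg$hr_range[2]),
      resp_rate = stats::runif(1, cfg$resp_range[1], cfg$resp_range[2]),
      skin_tier = sample(c("II", "III"), 1))
  }
  profs
}

# Feature matrix + responses for a cohort of profiles, one recording each.
.cohort_features <- function(profiles, cfg, seed_base, duration) {
  recs <- lapply(seq_along(profiles), function(i) {
    synth_recording(profiles[[i]], duration = duration,
                    quality = cfg$quality, rng_seed = seed_base + i,
                    fs = cfg$fs)
  })
  X <- build_feature_matrix(recs, window_s = cfg$window_s,
                            dc_cutoff = cfg$dc_cutoff)
  info <- attr(X, "info")
  list(X = X, sbp = info$sbp, dbp = info$dbp, info = info)
}

# One cuffless "reading": synthesize a short recording at the current true
# BP, extract the (single-window) features, run the calibrated estimator.
.cuffless_reading <- function(est, profile, cfg, seed) {
  rec <- synth_recording(profile, duration = cfg$estimate_duration,
                         quality = cfg$quality, rng_seed = seed, fs = cfg$fs)
  ac <- acdc_split(rec, cutoff = cfg$dc_cutoff)$ac
  pulses <- lapply(segment_pulses(ac, cfg$fs), detect_peaks)
  fv <- extract_features(pulses, cfg$fs)
  estimate_bp(est, fv)
}

#' Run the full simulated validation pipeline
#'
#' End-to-end: synthesize a pretraining cohort and fit the base GP models
#' with the shipped kernel constants; fine-tune on a second cohort;
#' follow a validation cohort through 5 weekly same-arm sequential
#' sessions with one cuff calibration per subject at week 1 (slots
#' BP1/BP2) and cuffless estimates at the test slots thereafter; pair the
#' readings; and compute the weekly validation reports. All randomness
#' flows from the single seed in the configuration.
#'
#' @param config A [default_config()] (or one with overrides).
#' @param out_dir Optional directory; when given, the reading log, pairs,
#'   and report are written there as CSV/JSON.
#' @return List with `report` (the [weekly_report()]), `pairs`, `log`
#'   (reading log), `truth_errors` (per-week estimate-minus-truth
#'   statistics), `models` (fine-tuned SBP/DBP models), and `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  .with_seed(cfg$seed, {
    # --- cohorts --------------------------------------------------------
    pre_prof <- .draw_cohort(cfg$pretrain_subjects, cfg, "w")
    fin_prof <- .draw_cohort(cfg$finetune_subjects, cfg, "a")
    val_prof <- .draw_cohort(cfg$n_subjects, cfg, "s")

    # --- training: pretrain then fine-tune ------------------------------
    pre <- .cohort_features(pre_prof, cfg, seed_base = 10000L,
                            duration = cfg$train_duration)
    init <- kernel_params(cfg$kernel_scale, cfg$signal_std)
    sbp_pre <- gpr_fit(pre$X, pre$sbp, init = init, fix_kernel = TRUE)
    dbp_pre <- gpr_fit(pre$X, pre$dbp, init = init, fix_kernel = TRUE)

    fin <- .cohort_features(fin_prof, cfg, seed_base = 20000L,
                            duration = cfg$train_duration)
    sbp_model <- gpr_finetune(sbp_pre, fin$X, fin$sbp)
    dbp_model <- gpr_finetune(dbp_pre, fin$X, fin$dbp)

    # --- weekly sessions ------------------------------------------------
    # per-subject true BP drifts slowly week to week (random walk)
    n_sub <- cfg$n_subjects
    truth_now <- data.frame(
      subject_id = vapply(val_prof, `[[`, "", "subject_id"),
      sbp = vapply(val_prof, `[[`, 0, "sbp_true"),
      dbp = vapply(val_prof, `[[`, 0, "dbp_true"))
    estimators <- vector("list", n_sub)
    log_rows <- list()
    truth_err <- list()
    seed_ctr <- 30000L
    add_log <- function(...) {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(...)
    }

    for (wk in seq_len(cfg$n_weeks)) {
      sched <- protocol_schedule(wk)
      for (i in seq_len(n_sub)) {
        prof <- val_prof[[i]]
        t0 <- 0
        for (k in seq_len(nrow(sched))) {
          slot <- sched$slot[k]
          # small slot-to-slot variation around the week's true BP
          sbp_slot <- truth_now$sbp[i] + stats::rnorm(1, 0, cfg$slot_bp_sd)
          dbp_slot <- truth_now$dbp[i] + stats::rnorm(1, 0, cfg$slot_bp_sd)
          prof_slot <- subject_profile(prof$subject_id,
                                       min(max(sbp_slot, 60), 200),
                                       min(max(dbp_slot, 40), 120),
                                       heart_rate = prof$heart_rate,
                                       resp_rate = prof$resp_rate,
                                       skin_tier = prof$skin_tier)
          if (sched$device[k] == "reference") {
            for (obs in c("obs1", "obs2")) {
              add_log(subject_id = prof$subject_id, week = wk, slot = slot,
                      device = "reference", observer = obs,
                      sbp = sbp_slot + stats::rnorm(1, 0, cfg$observer_sd),
                      dbp = dbp_slot + stats::rnorm(1, 0, cfg$observer_sd),
                      time = t0)
            }
            if (slot == "BP1") {
              # week-1 cuff calibration: anchor the estimator to the mean
              # of the two observers' cuff readings at the same features
              cuff <- log_rows[(length(log_rows) - 1L):length(log_rows)]
              cuff_sbp <- mean(vapply(cuff, `[[`, 0, "sbp"))
              cuff_dbp <- mean(vapply(cuff, `[[`, 0, "dbp"))
              seed_ctr <- seed_ctr + 1L
              rec <- synth_recording(prof_slot, cfg$estimate_duration,
                                     quality = cfg$quality,
                                     rng_seed = seed_ctr, fs = cfg$fs)
              ac <- acdc_split(rec, cutoff = cfg$dc_cutoff)$ac
              fv <- extract_features(
                lapply(segment_pulses(ac, cfg$fs), detect_peaks), cfg$fs)
              estimators[[i]] <- calibrate(sbp_model, dbp_model,
                                           cuff_sbp, cuff_dbp, fv, t0)
            }
          } else {
            if (slot == "BP2") {
              # calibration-mode test reading: by construction equals the cuff
              est <- estimate_bp(estimators[[i]],
                                 estimators[[i]]$cal$features_at_cal)
            } else {
              seed_ctr <- seed_ctr + 1L
              est <- .cuffless_reading(estimators[[i]], prof_slot, cfg, seed_ctr)
            }
            add_log(subject_id = prof$subject_id, week = wk, slot = slot,
                    device = "test", observer = "obs1",
                    sbp = est$sbp[1], dbp = est$dbp[1], time = t0)
            if (!slot %in% c("BP2")) {
              truth_err[[length(truth_err) + 1L]] <- data.frame(
                subject_id = prof$subject_id, week = wk, slot = slot,
                sbp_err = est$sbp[1] - sbp_slot,
                dbp_err = est$dbp[1] - dbp_slot)
            }
          }
          t0 <- t0 + 60
        }
      }
      truth_now$sbp <- pmin(pmax(
        truth_now$sbp + stats::rnorm(n_sub, 0, cfg$weekly_drift_sd), 70), 195)
      truth_now$dbp <- pmin(pmax(
        truth_now$dbp + stats::rnorm(n_sub, 0, cfg$weekly_drift_sd), 45), 115)
    }

    log <- do.call(rbind, log_rows)
    pairs <- build_pairs(log)
    report <- weekly_report(pairs, weeks = seq_len(cfg$n_weeks))
    errs <- do.call(rbind, truth_err)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(log, file.path(out_dir, "reading_log.csv"),
                       row.names = FALSE)
      utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                       row.names = FALSE)
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }

    list(report = report, pairs = pairs, log = log, truth_errors = errs,
         models = list(sbp = sbp_model, dbp = dbp_model), config = cfg)
  })
}

#' Per-week error statistics against ground truth
#'
#' Summarizes the pipeline's estimate-minus-truth errors per week and
#' target, with the ISO criterion-1 decision for each.
#'
#' @param truth_errors The `truth_errors` component of [run_pipeline()]'s
#'   result.
#' @return Data frame with one row per week x target: `mean_err`,
#'   `sd_err`, and `iso1_pass`.
#' @export
truth_error_summary <- function(truth_errors) {
  out <- list()
  for (wk in sort(unique(truth_errors$week))) {
    ew <- truth_errors[truth_errors$week == wk, ]
    for (tg in c("SBP", "DBP")) {
      e <- if (tg == "SBP") ew$sbp_err else ew$dbp_err
      out[[length(out) + 1L]] <- data.frame(
        week = wk, target = tg, n = length(e),
        mean_err = mean(e), sd_err = stats::sd(e),
        iso1_pass = iso_criterion1(mean(e), stats::sd(e)))
    }
  }
  do.call(rbind, out)
}
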