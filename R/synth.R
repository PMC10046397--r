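# Signal-to-noise ratio (dB) attached to each perceptual quality tier.
# Tiers are defined perceptually in the validation literature (can the
# systolic / diastolic peaks be told apart from noise?); the generator needs
# an operational knob, so each tier maps to an additive white-noise SNR.
.quality_snr_db <- c(fair = 5, good = 15, excellent = 30)

#' Quality tiers supported by the synthetic generator
#'
#' @return Character vector `c("fair", "good", "excellent")`, ordered from
#'   worst to best signal quality.
#' @export
quality_tiers <- function() names(.quality_snr_db)

#' Create a synthetic subject profile
#'
#' A subject profile bundles the physiological ground truth a synthetic
#' recording is generated from: true systolic/diastolic blood pressure,
#' heart rate, respiratory rate, and a skin tier that scales the pulsatile
#' amplitude (darker phototypes return less reflected green light).
#'
#' @param subject_id Character identifier.
#' @param sbp_true True systolic blood pressure, mmHg, in \[60, 200\].
#' @param dbp_true True diastolic blood pressure, mmHg, in \[40, 120\];
#'   must be strictly below `sbp_true`.
#' @param heart_rate Beats per minute, in \[40, 180\].
#' @param resp_rate Breaths per minute (drives the DC baseline oscillation);
#'   0 gives a constant baseline.
#' @param skin_tier `"II"` or `"III"` (Fitzpatrick phototype emulation;
#'   III scales pulsatile amplitude by 0.8).
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' subject_profile("s01", 120, 80)
subject_profile <- function(subject_id, sbp_true, dbp_true,
                            heart_rate = 70, resp_rate = 15,
                            skin_tier = c("II", "III")) {
  skin_tier <- match.arg(skin_tier)
  if (!is.numeric(sbp_true) || !is.numeric(dbp_true) ||
      sbp_true < 60 || sbp_true > 200) {
    stop("sbp_true must be in [60, 200] mmHg", call. = FALSE)
  }
  if (dbp_true < 40 || dbp_true > 120) {
    stop("dbp_true must be in [40, 120] mmHg", call. = FALSE)
  }
  if (sbp_true <= dbp_true) stop("sbp_true must exceed dbp_true", call. = FALSE)
  if (heart_rate < 40 || heart_rate > 180) {
    stop("heart_rate must be in [40, 180] bpm", call. = FALSE)
  }
  if (resp_rate < 0) stop("resp_rate must be non-negative", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         sbp_true = sbp_true, dbp_true = dbp_true,
         heart_rate = heart_rate, resp_rate = resp_rate,
         skin_tier = skin_tier),
    class = "subject_profile")
}

#' Map blood pressure to pulse morphology parameters
#'
#' Deterministic, injective link from (SBP, DBP) to the parameters of the
#' two-lobe (systolic + diastolic) Gaussian beat model. The link is an
#' assumption of the generator, chosen so downstream recovery is testable:
#'
#' * the systolic-lobe center (hence the systolic time) strictly
#'   *decreases* with SBP — higher pressure, faster upstroke;
#' * the systolic-lobe amplitude strictly increases with SBP;
#' * the diastolic-to-systolic amplitude ratio (hence the
#'   diastolic-to-systolic area ratio) strictly *increases* with DBP —
#'   higher diastolic pressure, stronger reflected wave.
#'
#' All timing parameters are fractions of the beat period, so the shape is
#' heart-rate invariant up to a time rescaling.
#'
#' @param sbp,dbp Blood pressure in mmHg; `sbp` in \[60, 200\], `dbp` in
#'   \[40, 120\], `sbp > dbp`.
#' @return A list of morphology parameters: `amp_sys` (a.u.),
#'   `sys_center_frac`, `width_sys_frac`, `amp_dia_ratio`,
#'   `dia_offset_frac`, `width_dia_frac` (all dimensionless fractions of
#'   the beat period except `amp_sys`).
#' @export
#' @examples
#' bp_to_morphology(120, 80)
bp_to_morphology <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp) || length(sbp) != 1L ||
      length(dbp) != 1L || !is.finite(sbp) || !is.finite(dbp)) {
    stop("sbp and dbp must be finite scalars", call. = FALSE)
  }
  if (sbp < 60 || sbp > 200) stop("sbp outside supported range [60, 200]", call. = FALSE)
  if (dbp < 40 || dbp > 120) stop("dbp outside supported range [40, 120]", call. = FALSE)
  if (sbp <= dbp) stop("sbp must exceed dbp", call. = FALSE)
  list(
    amp_sys         = 0.6 + 0.010 * (sbp - 60),
    sys_center_frac = 0.32 - 9e-4 * (sbp - 60),
    width_sys_frac  = 0.07,
    amp_dia_ratio   = 0.20 + 4.5e-3 * (dbp - 40),
    dia_offset_frac = 0.28,
    width_dia_frac  = 0.11)
}

# Noiseless one-beat AC waveform for a morphology at a given heart rate.
.clean_beat <- function(morph, heart_rate, fs) {
  period <- 60 / heart_rate
  n <- round(fs * period)
  t <- (seq_len(n) - 1) / fs
  cs <- morph$sys_center_frac * period
  cd <- (morph$sys_center_frac + morph$dia_offset_frac) * period
  ws <- morph$width_sys_frac * period
  wd <- morph$width_dia_frac * period
  morph$amp_sys * (exp(-(t - cs)^2 / (2 * ws^2)) +
                   morph$amp_dia_ratio * exp(-(t - cd)^2 / (2 * wd^2)))
}

.skin_scale <- function(skin_tier) if (identical(skin_tier, "III")) 0.8 else 1.0

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthesize a single PPG beat
#'
#' One heartbeat of pulsatile (AC) signal on a zero baseline: a systolic
#' Gaussian lobe plus a smaller, later diastolic lobe, with additive white
#' noise whose power is set by the quality tier (excellent 30 dB, good
#' 15 dB, fair 5 dB SNR). The fair tier additionally receives a random
#' baseline step emulating micromotion, with probability 1/2.
#'
#' @param profile A [subject_profile()].
#' @param quality One of [quality_tiers()].
#' @param rng_seed Integer seed; all randomness in the beat flows from it.
#' @param fs Sampling rate, Hz.
#' @param morph Optional morphology override (as from [bp_to_morphology()]);
#'   defaults to the profile's blood pressure mapped through
#'   [bp_to_morphology()].
#' @return Numeric vector of one beat (length `round(fs * 60/heart_rate)`),
#'   with attributes `clean` (noiseless beat) and `noise` (the realized
#'   additive noise), so the realized SNR can be audited.
#' @export
synth_pulse <- function(profile, quality = "excellent", rng_seed = 1L,
                        fs = 256, morph = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!quality %in% names(.quality_snr_db)) {
    stop("unknown quality tier: ", quality, call. = FALSE)
  }
  if (is.null(morph)) morph <- bp_to_morphology(profile$sbp_true, profile$dbp_true)
  clean <- .skin_scale(profile$skin_tier) * .clean_beat(morph, profile$heart_rate, fs)
  p_sig <- mean(clean^2)
  snr <- .quality_snr_db[[quality]]
  noise <- .with_seed(rng_seed, {
    sd_n <- if (p_sig > 0) sqrt(p_sig / 10^(snr / 10)) else 0
    n <- stats::rnorm(length(clean), 0, sd_n)
    if (identical(quality, "fair") && p_sig > 0 && stats::runif(1) < 0.5) {
      jump_at <- sample.int(length(clean), 1)
      jump_amp <- stats::runif(1, 0.3, 0.7) * max(clean) *
        sign(stats::runif(1) - 0.5)
      n[jump_at:length(n)] <- n[jump_at:length(n)] + jump_amp
    }
    n
  })
  structure(clean + noise, clean = clean, noise = noise, quality = quality)
}

#' Synthesize a PPG recording with known ground truth
#'
#' Concatenates beats (the AC component) and superposes a slow DC baseline:
#' a constant offset plus a respiration sinusoid at the profile's
#' respiratory rate. The DC-to-AC amplitude ratio is approximately 10:1,
#' typical of reflective PPG. Ground-truth (SBP, DBP) is recorded per
#' non-overlapping 15-s window. Beat-onset (foot) locations of the clean
#' waveform are logged so segmentation can be checked against the
#' generator itself.
#'
#' @inheritParams synth_pulse
#' @param duration Recording length in seconds; must cover at least one beat.
#' @param noise Add tier-level noise? Set `FALSE` for a noiseless record
#'   (useful as an oracle; the tier then only labels the record).
#' @return A `ppg_record`: list with `samples`, `fs`, `duration`, `truth`
#'   (data frame, one row per 15-s window), `quality_tier`, `profile`,
#'   `onsets` (1-based clean-signal foot indices), and attribute
#'   `ac_clean` (noiseless AC component, for oracle use).
#' @export
#' @examples
#' rec <- synth_recording(subject_profile("s01", 120, 80), duration = 15)
#' length(rec$samples) # 15 * 256
synth_recording <- function(profile, duration, quality = "excellent",
                            rng_seed = 1L, fs = 256, noise = TRUE) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!quality %in% names(.quality_snr_db)) {
    stop("unknown quality tier: ", quality, call. = FALSE)
  }
  period <- 60 / profile$heart_rate
  if (duration < period) {
    stop("duration must cover at least one beat (", signif(period, 3), " s)",
         call. = FALSE)
  }
  n_total <- round(fs * duration)
  morph <- bp_to_morphology(profile$sbp_true, profile$dbp_true)
  beat <- .skin_scale(profile$skin_tier) * .clean_beat(morph, profile$heart_rate, fs)
  n_beats <- ceiling(n_total / length(beat)) + 1L
  ac_clean <- rep(beat, n_beats)
  boundaries <- (seq_len(n_beats) - 1L) * length(beat) + 1L

  # The generator's own foot log: local minimum of the clean AC waveform in
  # a neighbourhood of each beat boundary (the inter-beat trough).
  half <- max(2L, round(0.15 * length(beat)))
  onsets <- vapply(boundaries, function(b) {
    lo <- max(1L, b - half); hi <- min(length(ac_clean), b + half)
    as.integer(lo + which.min(ac_clean[lo:hi]) - 1L)
  }, integer(1))

  ac_clean <- ac_clean[seq_len(n_total)]
  onsets <- onsets[onsets <= n_total]

  amp_ac <- max(ac_clean)
  dc_offset <- 10 * amp_ac
  t <- (seq_len(n_total) - 1) / fs
  resp <- if (profile$resp_rate > 0) {
    0.2 * amp_ac * sin(2 * pi * profile$resp_rate / 60 * t)
  } else {
    numeric(n_total)
  }
  dc <- dc_offset + resp

  snr <- .quality_snr_db[[quality]]
  p_sig <- mean(ac_clean^2)
  noise_vec <- if (!noise) numeric(n_total) else .with_seed(rng_seed, {
    sd_n <- if (p_sig > 0) sqrt(p_sig / 10^(snr / 10)) else 0
    n <- stats::rnorm(n_total, 0, sd_n)
    if (identical(quality, "fair") && p_sig > 0) {
      n_jump <- sample.int(3L, 1)
      for (j in seq_len(n_jump)) {
        jump_at <- sample.int(n_total, 1)
        jump_amp <- stats::runif(1, 0.3, 0.7) * amp_ac * sign(stats::runif(1) - 0.5)
        n[jump_at:n_total] <- n[jump_at:n_total] + jump_amp
      }
    }
    n
  })

  n_windows <- floor(duration / 15)
  truth <- if (n_windows >= 1) {
    data.frame(window = seq_len(n_windows),
               window_start = (seq_len(n_windows) - 1) * 15,
               sbp = profile$sbp_true, dbp = profile$dbp_true)
  } else {
    data.frame(window = integer(0), window_start = numeric(0),
               sbp = numeric(0), dbp = numeric(0))
  }

  structure(
    list(samples = ac_clean + dc + noise_vec, fs = fs, duration = duration,
         truth = truth, quality_tier = quality, profile = profile,
         onsets = onsets),
    ac_clean = ac_clean,
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat("<ppg_record> ", x$duration, " s @ ", x$fs, " Hz, quality '",
      x$quality_tier, "'", sep = "")
  if (!is.null(x$profile)) {
    cat(", truth ", x$profile$sbp_true, "/", x$profile$dbp_true, " mmHg",
        sep = "")
  }
  cat("\n")
  invisible(x)
}
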