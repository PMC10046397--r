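# Zero-phase Butterworth low-pass with mirror padding. The input mean is
# removed before filtering and restored afterwards so a constant signal
# passes through exactly (no warm-up transient).
.lowpass_zerophase <- function(x, fs, cutoff, order = 4L) {
  mu <- mean(x)
  xc <- x - mu
  pad <- min(length(xc) - 1L, round(3 * fs))
  xp <- c(rev(xc[seq_len(pad) + 1L]), xc, rev(xc[length(xc) - seq_len(pad)]))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_along(xc)] + mu
}

#' Split a PPG recording into AC and DC components
#'
#' The DC component (tissue/venous baseline plus respiration) is the
#' zero-phase low-pass of the input with a cutoff below the cardiac band;
#' the AC (pulsatile) component is the residual, so `ac + dc` reconstructs
#' the input exactly by construction.
#'
#' @param record A `ppg_record` (or any list with `samples` and `fs`).
#' @param cutoff Low-pass cutoff in Hz separating respiration (< 0.4 Hz)
#'   from the cardiac band (> 0.67 Hz at the 40 bpm floor). Default 0.5.
#' @param order Butterworth order (applied forward and backward). Default 4,
#'   which retains more than 95% of the power of cardiac content at
#'   1.2 Hz in the AC component.
#' @return List with numeric components `ac` and `dc`, each the length of
#'   the input.
#' @export
#' @examples
#' rec <- synth_recording(subject_profile("s", 120, 80), duration = 15)
#' parts <- acdc_split(rec)
#' max(abs(parts$ac + parts$dc - rec$samples)) # 0
acdc_split <- function(record, cutoff = 0.5, order = 4L) {
  x <- record$samples
  fs <- record$fs
  if (is.null(x) || is.null(fs)) stop("record must carry samples and fs", call. = FALSE)
  if (length(x) < 2 * fs) {
    stop("record shorter than 2 s: too short for filter warm-up", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  dc <- .lowpass_zerophase(x, fs, cutoff, order)
  list(ac = x - dc, dc = dc)
}

.moving_average <- function(x, k) {
  if (k <= 1L || length(x) < k) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # fill the ends so length and alignment are preserved
  half <- (k - 1L) %/% 2L
  y[seq_len(half)] <- y[half + 1L]
  y[(length(x) - half + 1L):length(x)] <- y[length(x) - half]
  y
}

#' Segment the AC component into individual pulses
#'
#' Beats are delimited foot-to-foot. Candidate upstrokes are contiguous
#' runs where the smoothed slope exceeds an adaptive threshold (half the
#' 98th percentile of positive slopes); the foot preceding each upstroke is
#' found by walking back to the local minimum. Beats whose duration falls
#' outside the physiological band \[60/180, 60/40\] s are discarded, as is
#' any trailing partial beat.
#'
#' @param ac Numeric AC sequence (from [acdc_split()]).
#' @param fs Sampling rate, Hz.
#' @return List of `ppg_pulse` objects, each with `samples` (foot-inclusive,
#'   next-foot-exclusive), `fs`, `start_index` (0-based offset of the foot
#'   in `ac`), `foot_index` (0, relative to the pulse), and unfilled peak
#'   landmarks. Empty list when no beats are found.
#' @export
segment_pulses <- function(ac, fs) {
  stopifnot(is.numeric(ac), fs > 0)
  if (length(ac) < 2L) return(list())
  # slope/foot search runs on an 8 Hz low-passed copy: beats live below
  # ~3 Hz, so this suppresses wideband noise without moving the landmarks
  sm <- if (length(ac) >= 2 * fs) {
    .lowpass_zerophase(ac, fs, cutoff = 8, order = 2L)
  } else {
    .moving_average(ac, 5L)
  }
  slope <- diff(sm)
  pos <- slope[slope > 0]
  if (length(pos) == 0L) return(list())
  thr <- 0.5 * stats::quantile(pos, 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(list())
  steep <- slope > thr
  if (!any(steep)) return(list())
  starts <- which(steep & !c(FALSE, steep[-length(steep)]))
  # merge upstroke starts closer than the 200-bpm refractory interval
  min_gap <- round(fs * 60 / 200)
  keep <- c(TRUE, diff(starts) >= min_gap)
  starts <- starts[keep]

  feet <- vapply(starts, function(s) {
    i <- s
    while (i > 1L && sm[i - 1L] <= sm[i]) i <- i - 1L
    # refine on the raw signal in a small neighbourhood
    lo <- max(1L, i - 5L); hi <- min(length(ac), i + 5L)
    lo + which.min(ac[lo:hi]) - 1L
  }, integer(1))
  feet <- sort(unique(feet))
  if (length(feet) < 2L) return(list())

  min_len <- round(fs * 60 / 180)
  max_len <- round(fs * 60 / 40)
  pulses <- list()
  for (k in seq_len(length(feet) - 1L)) {
    len <- feet[k + 1L] - feet[k]
    if (len < min_len || len > max_len) next
    pulses[[length(pulses) + 1L]] <- structure(
      list(samples = ac[feet[k]:(feet[k + 1L] - 1L)],
           fs = fs,
           start_index = feet[k] - 1L,
           foot_index = 0L,
           systolic_peak_index = NA_integer_,
           diastolic_peak_index = NA_integer_,
           quality = NA_character_,
           valid = TRUE),
      class = "ppg_pulse")
  }
  pulses
}

#' Locate systolic and diastolic peaks on a segmented pulse
#'
#' The systolic peak is the global maximum after the foot. The diastolic
#' peak is the most prominent local maximum after the systolic peak whose
#' prominence (height above the deepest intervening trough) exceeds
#' `prominence_frac` of the pulse amplitude; if no candidate qualifies the
#' landmark is left absent. A pulse whose global maximum sits past
#' 60% of the beat violates the systolic-first morphology and is
#' flagged invalid rather than silently corrected.
#'
#' @param pulse A `ppg_pulse` from [segment_pulses()].
#' @param prominence_frac Minimum diastolic prominence as a fraction of
#'   pulse amplitude. Default 0.05.
#' @return The pulse with `systolic_peak_index` and (possibly)
#'   `diastolic_peak_index` filled (0-based, relative to the pulse) and
#'   `valid` updated.
#' @export
detect_peaks <- function(pulse, prominence_frac = 0.05) {
  stopifnot(inherits(pulse, "ppg_pulse"))
  x <- pulse$samples
  n <- length(x)
  sm <- .moving_average(x, 5L)
  sys_i <- which.max(sm)
  amp <- sm[sys_i] - sm[1L]
  pulse$systolic_peak_index <- sys_i - 1L
  pulse$valid <- TRUE
  if (sys_i <= 1L || sys_i > 0.6 * n) {
    # peak on the foot itself, or a dominant late lobe: not systolic-first
    pulse$valid <- FALSE
    pulse$diastolic_peak_index <- NA_integer_
    return(pulse)
  }
  dia <- NA_integer_
  if (sys_i < n - 1L) {
    idx <- (sys_i + 1L):(n - 1L)
    is_max <- sm[idx] >= sm[idx - 1L] & sm[idx] >= sm[idx + 1L]
    cand <- idx[is_max]
    if (length(cand) > 0L) {
      prom <- vapply(cand, function(i) sm[i] - min(sm[sys_i:i]), numeric(1))
      ok <- prom >= prominence_frac * amp & sm[cand] < sm[sys_i]
      if (any(ok)) dia <- cand[ok][which.max(prom[ok])] - 1L
    }
  }
  pulse$diastolic_peak_index <- dia
  pulse
}

# In-band vs high-frequency power ratio, in dB. The pulse is smoothed with a
# zero-phase 10 Hz low-pass (cardiac morphology lives well below 10 Hz); the
# residual is taken as noise.
.pulse_snr_db <- function(pulse) {
  x <- pulse$samples
  if (length(x) < 12L) return(-Inf)
  sm <- .lowpass_zerophase(x, pulse$fs, cutoff = 10, order = 4L)
  res <- x - sm
  p_sig <- mean((sm - mean(sm))^2)
  p_res <- mean(res^2)
  if (p_res < 1e-20 * max(p_sig, 1e-300)) return(Inf)
  10 * log10(p_sig / p_res)
}

#' Grade the signal quality of a pulse
#'
#' Operationalizes the three perceptual quality levels used by human
#' raters: *excellent* — both peaks detected and pulse SNR at or above the
#' threshold; *good* — the systolic peak is clear (SNR at/above threshold)
#' but no diastolic peak is detectable; *fair* — otherwise (peaks cannot be
#' distinguished from noise, or the pulse is morphologically invalid).
#'
#' @param pulse A `ppg_pulse`; peak detection is run first if the landmarks
#'   are unfilled.
#' @param snr_threshold_db SNR (dB) above which the systolic peak is
#'   considered clearly detectable. Default 12.
#' @param prominence_frac Passed to [detect_peaks()] when needed.
#' @return The pulse with its `quality` field set to one of
#'   `"fair"`, `"good"`, `"excellent"`.
#' @export
grade_quality <- function(pulse, snr_threshold_db = 12, prominence_frac = 0.05) {
  stopifnot(inherits(pulse, "ppg_pulse"))
  if (is.na(pulse$systolic_peak_index)) {
    pulse <- detect_peaks(pulse, prominence_frac)
  }
  snr <- .pulse_snr_db(pulse)
  pulse$quality <-
    if (!isTRUE(pulse$valid) || snr < snr_threshold_db) {
      "fair"
    } else if (!is.na(pulse$diastolic_peak_index)) {
      "excellent"
    } else {
      "good"
    }
  pulse
}

#' @export
print.ppg_pulse <- function(x, ...) {
  cat("<ppg_pulse> ", length(x$samples), " samples @ ", x$fs, " Hz",
      "; systolic peak ", x$systolic_peak_index,
      ", diastolic peak ", x$diastolic_peak_index,
      if (!is.na(x$quality)) paste0(", quality '", x$quality, "'"), "\n",
      sep = "")
  invisible(x)
}
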