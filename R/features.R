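#' Names and order of the ten waveform features
#'
#' The fixed column order of every feature vector and feature matrix:
#' systolic area over total area, diastolic area over total area, systolic
#' area over pulse amplitude (s), diastolic area over pulse amplitude (s),
#' maximal amplitude over time (upstroke-slope proxy, amplitude/s),
#' systolic time (s), diastolic time (s), mean peak-to-peak interval (s),
#' pulse amplitude (a.u.), and pulse width at half amplitude (s).
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("sys_area_over_total", "dia_area_over_total",
    "sys_area_over_amp", "dia_area_over_amp",
    "max_amp_over_time", "systolic_time", "diastolic_time",
    "mean_pp_interval", "pulse_amplitude", "pulse_width_half_amp")
}

# Width (s) of the region around the systolic peak where the
# baseline-subtracted pulse exceeds half its amplitude, with linear
# interpolation at the crossings so the width varies continuously.
.half_amp_width <- function(y, sys_i, fs) {
  half <- y[sys_i] / 2
  n <- length(y)
  # left crossing
  i <- sys_i
  while (i > 1L && y[i - 1L] >= half) i <- i - 1L
  left <- if (i == 1L) 1 else {
    (i - 1) + (half - y[i - 1L]) / (y[i] - y[i - 1L])
  }
  # right crossing
  j <- sys_i
  while (j < n && y[j + 1L] >= half) j <- j + 1L
  right <- if (j == n) n else {
    j + (y[j] - half) / (y[j] - y[j + 1L])
  }
  (right - left) / fs
}

# Sub-sample offset of a local maximum by 3-point parabolic interpolation;
# keeps time-valued features continuous in the underlying morphology
# instead of quantized to the sampling grid.
.parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (!is.finite(denom) || abs(denom) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (y[i - 1L] - y[i + 1L]) / denom))
}

.pulse_features <- function(pulse) {
  x <- pulse$samples
  fs <- pulse$fs
  sys_i <- pulse$systolic_peak_index + 1L  # to 1-based
  y <- x - x[1L]                           # baseline-subtract at the foot
  t <- (seq_along(y) - 1) / fs
  if (sys_i <= 1L || sys_i >= length(y)) return(NULL)
  amp <- y[sys_i]
  if (!is.finite(amp) || amp <= 0) return(NULL)
  delta <- .parabolic_offset(y, sys_i)
  a_tot <- pracma::trapz(t, y)
  a_sys <- pracma::trapz(t[1:sys_i], y[1:sys_i])
  # partial strip between the sample peak and the refined peak time, so the
  # systolic/diastolic split point moves continuously
  if (delta > 0) {
    y_at <- y[sys_i] + delta * (y[sys_i + 1L] - y[sys_i])
    a_sys <- a_sys + (delta / fs) * (y[sys_i] + y_at) / 2
  } else if (delta < 0) {
    y_at <- y[sys_i] + delta * (y[sys_i] - y[sys_i - 1L])
    a_sys <- a_sys + (delta / fs) * (y[sys_i] + y_at) / 2
  }
  a_dia <- a_tot - a_sys
  if (!is.finite(a_tot) || a_tot <= 0) return(NULL)
  t_sys <- t[sys_i] + delta / fs
  t_dia <- t[length(t)] - t_sys
  c(sys_area_over_total = a_sys / a_tot,
    dia_area_over_total = a_dia / a_tot,
    sys_area_over_amp = a_sys / amp,
    dia_area_over_amp = a_dia / amp,
    max_amp_over_time = amp / t_sys,
    systolic_time = t_sys,
    diastolic_time = t_dia,
    mean_pp_interval = NA_real_,  # window-level, filled by extract_features
    pulse_amplitude = amp,
    pulse_width_half_amp = .half_amp_width(y, sys_i, fs))
}

#' Extract the ten-dimensional feature vector from one window of pulses
#'
#' Computes per-pulse quantities on baseline-subtracted beats (systolic
#' region foot to systolic peak, diastolic region systolic peak to beat
#' end, areas by trapezoidal integration) and summarizes each across the
#' window by the median. The mean peak-to-peak interval is the mean
#' spacing of successive systolic peaks, which is why at least two usable
#' pulses are required.
#'
#' @param pulses List of `ppg_pulse` objects from one window, with peaks
#'   detected ([detect_peaks()] is applied to unfilled pulses).
#' @param fs Sampling rate, Hz (must match the pulses).
#' @return Named numeric vector of length 10 in [feature_names()] order,
#'   with attribute `n_pulses`.
#' @export
#' @examples
#' rec <- synth_recording(subject_profile("s", 120, 80), duration = 15)
#' ac <- acdc_split(rec)$ac
#' extract_features(segment_pulses(ac, rec$fs), rec$fs)
extract_features <- function(pulses, fs) {
  pulses <- lapply(pulses, function(p) {
    if (is.na(p$systolic_peak_index)) detect_peaks(p) else p
  })
  pulses <- Filter(function(p) isTRUE(p$valid), pulses)
  per_pulse <- lapply(pulses, .pulse_features)
  kept <- which(!vapply(per_pulse, is.null, logical(1)))
  rows <- per_pulse[kept]
  if (length(rows) < 2L) {
    stop("window rejected: fewer than 2 usable pulses", call. = FALSE)
  }
  peak_times <- vapply(pulses[kept], function(p) {
    (p$start_index + p$systolic_peak_index) / fs
  }, numeric(1))
  m <- do.call(rbind, rows)
  fv <- apply(m, 2, stats::median)
  fv["mean_pp_interval"] <- mean(diff(sort(peak_times)))
  fv <- fv[feature_names()]
  attr(fv, "n_pulses") <- length(rows)
  fv
}

#' Build the N x 10 feature matrix from a set of recordings
#'
#' Each recording is decomposed with [acdc_split()], segmented with
#' [segment_pulses()], and cut into non-overlapping 15-s windows aligned
#' to the record start (`floor(duration / window_s)` windows). Pulses are
#' assigned to windows by foot time; windows with fewer than two usable
#' pulses are rejected and logged.
#'
#' @param records List of `ppg_record` objects.
#' @param window_s Window length in seconds (default 15).
#' @param dc_cutoff Low-pass cutoff for [acdc_split()], Hz.
#' @return A `feature_matrix`: numeric matrix (one row per accepted
#'   window, 10 columns in [feature_names()] order) with attributes
#'   `info` (data frame: record index, window, window start, and truth
#'   SBP/DBP when present) and `rejected` (data frame of rejected
#'   windows and reasons).
#' @export
build_feature_matrix <- function(records, window_s = 15, dc_cutoff = 0.5) {
  if (inherits(records, "ppg_record")) records <- list(records)
  rows <- list()
  info <- list()
  rejected <- list()
  for (r in seq_along(records)) {
    rec <- records[[r]]
    parts <- acdc_split(rec, cutoff = dc_cutoff)
    pulses <- segment_pulses(parts$ac, rec$fs)
    pulses <- lapply(pulses, detect_peaks)
    n_win <- floor(rec$duration / window_s)
    if (n_win < 1L) next
    foot_t <- vapply(pulses, function(p) p$start_index / rec$fs, numeric(1))
    for (w in seq_len(n_win)) {
      in_win <- pulses[foot_t >= (w - 1) * window_s & foot_t < w * window_s]
      fv <- tryCatch(extract_features(in_win, rec$fs), error = function(e) e)
      if (inherits(fv, "error")) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          record = r, window = w, reason = conditionMessage(fv))
        next
      }
      rows[[length(rows) + 1L]] <- fv
      tr <- rec$truth
      has_truth <- is.data.frame(tr) && w <= nrow(tr)
      info[[length(info) + 1L]] <- data.frame(
        record = r, window = w, window_start = (w - 1) * window_s,
        sbp = if (has_truth) tr$sbp[w] else NA_real_,
        dbp = if (has_truth) tr$dbp[w] else NA_real_)
    }
  }
  if (length(rows) == 0L) stop("no windows accepted", call. = FALSE)
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- feature_names()
  structure(X,
            info = do.call(rbind, info),
            rejected = if (length(rejected)) do.call(rbind, rejected) else NULL,
            class = c("feature_matrix", class(X)))
}

#' Storage footprint of a feature matrix in bits
#'
#' Bookkeeping helper for embedded deployment: the size of an
#' `n_windows x n_features` matrix stored at a given float precision.
#'
#' @param n_windows Number of rows (15-s windows).
#' @param n_features Number of columns; default 10.
#' @param bits_per_value Bits per stored value; default 32 (single float).
#' @return Size in bits.
#' @export
#' @examples
#' feature_matrix_bits(1389) # 444480
feature_matrix_bits <- function(n_windows, n_features = 10L, bits_per_value = 32L) {
  as.numeric(n_windows) * n_features * bits_per_value
}
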