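#' Write / read a PPG record as CSV with a JSON sidecar
#'
#' The CSV carries columns `t_seconds` and `amplitude`; the sidecar
#' (`<path>.json`) stores the sampling rate, quality tier, subject
#' profile, and per-window ground truth. On read, if the sidecar is
#' absent the sampling rate is inferred from the timestamps, which must
#' be uniform to within 0.1%.
#'
#' @param record A `ppg_record`.
#' @param path CSV file path.
#' @return `write_record` returns `path` invisibly; `read_record` returns
#'   a `ppg_record`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  t <- (seq_along(record$samples) - 1) / record$fs
  utils::write.csv(data.frame(t_seconds = t, amplitude = record$samples),
                   path, row.names = FALSE)
  side <- list(fs = record$fs, duration = record$duration,
               quality_tier = record$quality_tier,
               profile = unclass(record$profile),
               truth = record$truth, onsets = record$onsets)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @param declared_fs Optional sampling rate (Hz) to validate the
#'   timestamps against (tolerance 0.1%).
#' @export
read_record <- function(path, declared_fs = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("t_seconds", "amplitude") %in% names(df))) {
    stop("CSV must have columns t_seconds, amplitude", call. = FALSE)
  }
  dt <- diff(df$t_seconds)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 0.001 * dt0)) {
    stop("non-uniform sampling: timestamp jitter exceeds 0.1%", call. = FALSE)
  }
  fs <- 1 / dt0
  side_path <- paste0(path, ".json")
  profile <- NULL; truth <- NULL; tier <- NULL; onsets <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fs <- side$fs
    tier <- side$quality_tier
    truth <- side$truth
    onsets <- side$onsets
    if (!is.null(side$profile)) {
      profile <- structure(as.list(side$profile), class = "subject_profile")
    }
  }
  if (!is.null(declared_fs) && abs(fs - declared_fs) > 0.001 * declared_fs) {
    stop("sampling rate mismatch: timestamps imply ", signif(fs, 6),
         " Hz, declared ", declared_fs, " Hz", call. = FALSE)
  }
  structure(
    list(samples = df$amplitude, fs = fs,
         duration = length(df$amplitude) / fs,
         truth = truth, quality_tier = tier, profile = profile,
         onsets = onsets),
    class = "ppg_record")
}
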