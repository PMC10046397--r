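#' Calibrate cuffless estimates against a cuff reference
#'
#' PPG features track *changes* in blood pressure; a cuff reading anchors
#' them to absolute pressure. Calibration stores, per target, the additive
#' offset `cuff - model prediction` at the calibration feature vector, so
#' the estimate at the calibration operating point equals the cuff
#' reading exactly.
#'
#' @param sbp_model,dbp_model Fitted [gpr_fit()] models for SBP and DBP.
#' @param cuff_sbp,cuff_dbp Cuff reference reading, mmHg; `cuff_sbp` must
#'   exceed `cuff_dbp` (guard against manual entry errors).
#' @param features Feature vector (length 10) observed at calibration time.
#' @param timestamp Seconds (arbitrary epoch).
#' @return An object of class `calibrated_estimator`.
#' @export
calibrate <- function(sbp_model, dbp_model, cuff_sbp, cuff_dbp,
                      features, timestamp = 0) {
  stopifnot(inherits(sbp_model, "gpr_model"), inherits(dbp_model, "gpr_model"))
  if (!is.finite(cuff_sbp) || !is.finite(cuff_dbp) || cuff_sbp <= cuff_dbp) {
    stop("invalid cuff reading: systolic must exceed diastolic", call. = FALSE)
  }
  fv <- as.numeric(features)
  pred_s <- predict(sbp_model, fv)$mean
  pred_d <- predict(dbp_model, fv)$mean
  structure(
    list(sbp_model = sbp_model, dbp_model = dbp_model,
         cal = list(cuff_sbp = cuff_sbp, cuff_dbp = cuff_dbp,
                    features_at_cal = fv, timestamp = timestamp),
         offsets = c(sbp = cuff_sbp - pred_s, dbp = cuff_dbp - pred_d)),
    class = "calibrated_estimator")
}

#' Estimate absolute blood pressure from features
#'
#' Posterior mean of each GP model plus the stored calibration offset;
#' the posterior standard deviation is passed through unchanged. A result
#' with SBP not exceeding DBP is flagged invalid rather than silently
#' corrected.
#'
#' @param est A `calibrated_estimator` from [calibrate()].
#' @param features Feature vector (length 10) or matrix (rows = windows).
#' @return Data frame with columns `sbp`, `dbp`, `sbp_std`, `dbp_std`
#'   (mmHg) and `valid`.
#' @export
estimate_bp <- function(est, features) {
  if (!inherits(est, "calibrated_estimator") || is.null(est$cal)) {
    stop("estimator is not calibrated: absolute estimates refused", call. = FALSE)
  }
  if (is.null(dim(features))) features <- matrix(as.numeric(features), nrow = 1)
  ps <- predict(est$sbp_model, features)
  pd <- predict(est$dbp_model, features)
  sbp <- ps$mean + est$offsets[["sbp"]]
  dbp <- pd$mean + est$offsets[["dbp"]]
  data.frame(sbp = sbp, dbp = dbp, sbp_std = ps$sd, dbp_std = pd$sd,
             valid = sbp > dbp)
}

# ---- calibration-session state machine -------------------------------------

.cal_states <- c("default", "paired", "started", "measured",
                 "transferred", "calibrated", "confirmed", "aborted")
.cal_events <- c("pair", "start", "cuff_reading", "transfer", "calibrate", "ack")

#' Start a calibration session
#'
#' The automated cuff-to-cuffless calibration workflow is a deterministic
#' eight-state machine: `default` (reporting mode) -> `paired` ->
#' `started` -> `measured` (cuff reading taken) -> `transferred` (reading
#' sent to the wearable) -> `calibrated` (model anchored) -> `confirmed`
#' (calibration mode complete), plus a terminal `aborted` state reached by
#' any out-of-order event. Replaying the event just consumed is idempotent.
#'
#' @return An object of class `calibration_session` in state `"default"`.
#' @export
#' @examples
#' s <- calibration_session()
#' for (e in c("pair", "start", "cuff_reading", "transfer", "calibrate", "ack"))
#'   s <- session_step(s, e)
#' s$state # "confirmed"
calibration_session <- function() {
  structure(list(state = "default", last_event = NA_character_,
                 log = character(0), diagnostic = NA_character_),
            class = "calibration_session")
}

#' Advance a calibration session by one event
#'
#' @param session A `calibration_session`.
#' @param event One of `"pair"`, `"start"`, `"cuff_reading"`,
#'   `"transfer"`, `"calibrate"`, `"ack"`.
#' @return The updated session. Out-of-order events move the session to
#'   `"aborted"` with a diagnostic; duplicates of the last consumed event
#'   leave the state unchanged.
#' @export
session_step <- function(session, event) {
  stopifnot(inherits(session, "calibration_session"))
  if (!event %in% .cal_events) {
    stop("unknown event: ", event, call. = FALSE)
  }
  session$log <- c(session$log, event)
  if (identical(session$state, "aborted")) return(session)
  # idempotent replay of the event that produced the current state
  if (identical(event, session$last_event)) return(session)
  expected <- .cal_events[match(session$state, .cal_states)]
  if (identical(session$state, "confirmed") || !identical(event, expected)) {
    session$diagnostic <- sprintf(
      "out-of-order event '%s' in state '%s' (expected '%s')",
      event, session$state,
      if (identical(session$state, "confirmed")) "<none>" else expected)
    session$state <- "aborted"
    return(session)
  }
  session$state <- .cal_states[match(session$state, .cal_states) + 1L]
  session$last_event <- event
  session
}

#' @export
print.calibration_session <- function(x, ...) {
  cat("<calibration_session> state '", x$state, "'", sep = "")
  if (!is.na(x$diagnostic)) cat(" (", x$diagnostic, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.calibrated_estimator <- function(x, ...) {
  cat("<calibrated_estimator> offsets: SBP ", signif(x$offsets[["sbp"]], 4),
      ", DBP ", signif(x$offsets[["dbp"]], 4), " mmHg; cuff ",
      x$cal$cuff_sbp, "/", x$cal$cuff_dbp, " mmHg at t = ",
      x$cal$timestamp, " s\n", sep = "")
  invisible(x)
}
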