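#' Same-arm sequential measurement schedule for one weekly session
#'
#' Week 1 alternates reference and test readings over eight slots,
#' starting with the reference device: BP1 (reference, 'calibrated'),
#' BP2 (test, 'calibration'), BP3/BP5/BP7 (reference), BP4/BP6/BP8
#' (test). The two calibration slots are not required at follow-up, so
#' weeks 2-5 run BP3 through BP8 only. A minimum interval of 60 s
#' separates consecutive readings.
#'
#' @param week Integer in 1..5.
#' @return Data frame with columns `slot` (`"BP1"`..`"BP8"`), `device`
#'   (`"reference"` for odd slots, `"test"` for even), and `calibration`
#'   (logical; TRUE only for BP1/BP2 in week 1).
#' @export
#' @examples
#' nrow(protocol_schedule(1)) # 8
#' nrow(protocol_schedule(2)) # 6
protocol_schedule <- function(week) {
  if (!is.numeric(week) || length(week) != 1L || week != round(week) ||
      week < 1 || week > 5) {
    stop("week must be an integer in 1..5", call. = FALSE)
  }
  slots <- if (week == 1) 1:8 else 3:8
  data.frame(
    slot = paste0("BP", slots),
    device = ifelse(slots %% 2 == 1, "reference", "test"),
    calibration = week == 1 & slots <= 2,
    stringsAsFactors = FALSE)
}

#' Build test-vs-reference comparison pairs from a reading log
#'
#' Each non-calibration reference slot is paired with the immediately
#' following test slot (BP3 with BP4, BP5 with BP6, BP7 with BP8). The
#' reference value is the arithmetic mean of the two blinded observers'
#' readings at that slot; supervisor readings never enter pairing. A
#' complete subject-week therefore yields three pairs; pairs missing an
#' observer or a test reading are dropped and reported via the
#' `dropped` attribute.
#'
#' @param readings Data frame with columns `subject_id`, `week`, `slot`,
#'   `device` (`"reference"`/`"test"`), `observer` (`"obs1"`, `"obs2"`,
#'   `"supervisor"`), `sbp`, `dbp`, and optionally `time` (s).
#' @return Data frame of comparison pairs with columns `subject_id`,
#'   `week`, `ref_slot`, `ref_sbp`, `ref_dbp`, `test_sbp`, `test_dbp`.
#' @export
build_pairs <- function(readings) {
  req <- c("subject_id", "week", "slot", "device", "observer", "sbp", "dbp")
  if (!all(req %in% names(readings))) {
    stop("readings must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  slot_num <- as.integer(sub("^BP", "", readings$slot))
  bad <- (slot_num %% 2 == 1 & readings$device != "reference") |
         (slot_num %% 2 == 0 & readings$device != "test")
  if (any(bad)) {
    stop("slot/device mismatch: odd slots must be reference, even slots test",
         call. = FALSE)
  }
  pairs <- list()
  dropped <- list()
  for (key in unique(paste(readings$subject_id, readings$week, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub_id <- parts[1]; wk <- as.numeric(parts[2])
    grp <- readings[readings$subject_id == sub_id & readings$week == wk, ]
    for (ref_slot in c(3L, 5L, 7L)) {
      obs <- grp[grp$slot == paste0("BP", ref_slot) &
                 grp$observer %in% c("obs1", "obs2"), ]
      tst <- grp[grp$slot == paste0("BP", ref_slot + 1L) &
                 grp$observer != "supervisor", ]
      if (nrow(obs) < 2L || nrow(tst) < 1L) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          subject_id = sub_id, week = wk, ref_slot = paste0("BP", ref_slot),
          reason = if (nrow(obs) < 2L) "missing observer reading"
                   else "missing test reading")
        next
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        subject_id = sub_id, week = wk, ref_slot = paste0("BP", ref_slot),
        ref_sbp = mean(obs$sbp), ref_dbp = mean(obs$dbp),
        test_sbp = tst$sbp[1L], test_dbp = tst$dbp[1L])
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(subject_id = character(0), week = numeric(0),
               ref_slot = character(0), ref_sbp = numeric(0),
               ref_dbp = numeric(0), test_sbp = numeric(0),
               test_dbp = numeric(0))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  out
}

#' Simulate a complete reading log for one weekly session
#'
#' Fills every slot of [protocol_schedule()] for each subject: both
#' blinded observers (plus the supervisor on the test device) at
#' reference slots, one device reading at test slots. Readings are the
#' subject's true pressure plus independent Gaussian measurement noise.
#' Intended for protocol-level testing; the full pipeline replaces the
#' test-slot values with actual cuffless estimates.
#'
#' @param truth Data frame with columns `subject_id`, `sbp`, `dbp` (true
#'   pressures, mmHg).
#' @param week Integer in 1..5.
#' @param observer_sd Per-reading measurement noise SD, mmHg.
#' @param seed Integer seed.
#' @return A reading-log data frame suitable for [build_pairs()].
#' @export
simulate_session_log <- function(truth, week = 1, observer_sd = 1.5, seed = 1L) {
  sched <- protocol_schedule(week)
  .with_seed(seed, {
    rows <- list()
    t0 <- 0
    for (i in seq_len(nrow(truth))) {
      for (k in seq_len(nrow(sched))) {
        slot <- sched$slot[k]
        observers <- if (sched$device[k] == "reference") c("obs1", "obs2")
                     else c("obs1", "supervisor")
        for (obs in observers) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = truth$subject_id[i], week = week, slot = slot,
            device = sched$device[k], observer = obs,
            sbp = truth$sbp[i] + stats::rnorm(1, 0, observer_sd),
            dbp = truth$dbp[i] + stats::rnorm(1, 0, observer_sd),
            time = t0)
        }
        t0 <- t0 + 60  # minimum 60-s inter-reading interval
      }
    }
    do.call(rbind, rows)
  })
}
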