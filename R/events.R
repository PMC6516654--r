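#' Dose event (zero-order intravenous infusion)
#'
#' @param start infusion start, h.
#' @param amount dose, mg (>= 0).
#' @param infusion_duration infusion length, h (> 0).  A bolus is represented
#'   as a short infusion.
#' @return data.frame with one row per event; rows may be concatenated with
#'   `rbind()`.
#' @export
dose_event <- function(start, amount, infusion_duration) {
  stopifnot(length(start) == length(amount),
            length(start) == length(infusion_duration))
  if (any(start < 0)) stop("dose start times must be >= 0", call. = FALSE)
  if (any(amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(infusion_duration <= 0))
    stop("infusion_duration must be > 0", call. = FALSE)
  data.frame(start = start, amount = amount,
             infusion_duration = infusion_duration)
}

#' Dialysis session
#'
#' While a session runs, the extracorporeal clearance term `Qec * Eec` is
#' added to the drug's total clearance; outside sessions it is zero.
#'
#' @param start session start, h.
#' @param duration session length, h (> 0); 4 h is the usual outpatient
#'   schedule.
#' @param qec_ml_min extracorporeal blood flow, mL/min (>= 0).
#' @return data.frame with one row per session.
#' @export
dialysis_session <- function(start, duration = 4, qec_ml_min = 250) {
  n <- length(start)
  duration <- rep_len(duration, n)
  qec_ml_min <- rep_len(qec_ml_min, n)
  if (any(start < 0)) stop("session start times must be >= 0", call. = FALSE)
  if (any(duration <= 0)) stop("session duration must be > 0", call. = FALSE)
  if (any(qec_ml_min < 0)) stop("Qec must be >= 0", call. = FALSE)
  out <- data.frame(start = start, duration = duration,
                    qec_ml_min = qec_ml_min)
  check_sessions(out)
  out
}

check_sessions <- function(sessions) {
  if (is.null(sessions) || nrow(sessions) == 0) return(invisible(NULL))
  o <- order(sessions$start)
  s <- sessions[o, , drop = FALSE]
  ends <- s$start + s$duration
  if (any(s$start[-1] < ends[-nrow(s)] - 1e-9))
    stop("dialysis sessions overlap", call. = FALSE)
  invisible(NULL)
}
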