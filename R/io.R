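#' Cohort container
#'
#' A `pk_cohort` is a list of patients; each patient is a list with elements
#' `record` (a [patient_record()]), `doses`, `sessions` (see [dose_event()],
#' [dialysis_session()]) and `obs` (data.frame `time`, `conc`).  All times
#' are hours from the patient's first event.
#'
#' @param patients list of patient entries as described above.
#' @return object of class `pk_cohort`.
#' @export
pk_cohort <- function(patients) {
  for (p in patients) {
    stopifnot(inherits(p$record, "patient_record"))
    if (!is.null(p$obs) && nrow(p$obs)) {
      if (is.unsorted(p$obs$time))
        stop("observation times must be non-decreasing for patient ",
             p$record$id, call. = FALSE)
      if (any(p$obs$conc <= 0))
        stop("observed concentrations must be positive for patient ",
             p$record$id, call. = FALSE)
    }
    check_sessions(p$sessions)
  }
  names(patients) <- vapply(patients, function(p) p$record$id, character(1))
  structure(patients, class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  nobs <- vapply(x, function(p) nrow(p$obs), integer(1))
  cat(sprintf("<pk_cohort> %d patients, %d observations\n", length(x),
              sum(nobs)))
  invisible(x)
}

n_observations <- function(cohort) {
  sum(vapply(cohort, function(p) nrow(p$obs), integer(1)))
}

DEMO_COLS <- c("id", "age", "weight_kg", "height_cm", "sex",
               "serum_creat_mmol_L", "urine_creat_24h_mmol",
               "serum_urea_mmol_L", "urine_urea_24h_mmol")
EVENT_COLS <- c("id", "time_h", "event", "amount_mg", "infusion_h",
                "qec_ml_min", "conc_mg_L")

#' Read a cohort from demographics and event-record CSV files
#'
#' The event file has one row per event with columns
#' `id, time_h, event, amount_mg, infusion_h, qec_ml_min, conc_mg_L` where
#' `event` is one of `dose`, `obs`, `hd_start`, `hd_end`; the demographics
#' file has columns
#' `id, age, weight_kg, height_cm, sex, serum_creat_mmol_L,
#' urine_creat_24h_mmol, serum_urea_mmol_L, urine_urea_24h_mmol`.
#' Validation cross-checks that every event id has demographics, that
#' `hd_start`/`hd_end` pairs match up, and that times are non-negative;
#' errors name the offending row.
#'
#' @param demographics_path,events_path CSV paths.
#' @return a [pk_cohort()].
#' @export
read_cohort <- function(demographics_path, events_path) {
  demo <- read.csv(demographics_path, stringsAsFactors = FALSE)
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  if (!all(DEMO_COLS %in% names(demo)))
    stop("demographics file must have columns ",
         paste(DEMO_COLS, collapse = ", "), call. = FALSE)
  if (!all(EVENT_COLS %in% names(ev)))
    stop("event file must have columns ", paste(EVENT_COLS, collapse = ", "),
         call. = FALSE)
  demo$id <- as.character(demo$id); ev$id <- as.character(ev$id)
  bad <- which(!ev$event %in% c("dose", "obs", "hd_start", "hd_end"))
  if (length(bad))
    stop("unknown event type in row ", bad[1], ": ", ev$event[bad[1]],
         call. = FALSE)
  orphan <- which(!ev$id %in% demo$id)
  if (length(orphan))
    stop("event row ", orphan[1], " has id '", ev$id[orphan[1]],
         "' with no demographics entry", call. = FALSE)
  if (any(ev$time_h < 0))
    stop("event row ", which(ev$time_h < 0)[1], " has negative time",
         call. = FALSE)
  patients <- lapply(seq_len(nrow(demo)), function(i) {
    rec <- patient_record(demo$id[i], demo$age[i], demo$weight_kg[i],
                          demo$height_cm[i], demo$sex[i],
                          demo$serum_creat_mmol_L[i],
                          demo$urine_creat_24h_mmol[i],
                          demo$serum_urea_mmol_L[i],
                          demo$urine_urea_24h_mmol[i])
    e <- ev[ev$id == demo$id[i], , drop = FALSE]
    d <- e[e$event == "dose", , drop = FALSE]
    doses <- dose_event(d$time_h, d$amount_mg, d$infusion_h)
    hs <- e[e$event == "hd_start", , drop = FALSE]
    he <- e[e$event == "hd_end", , drop = FALSE]
    if (nrow(hs) != nrow(he))
      stop("unpaired hd_start/hd_end events for patient ", demo$id[i],
           call. = FALSE)
    hs <- hs[order(hs$time_h), , drop = FALSE]
    he <- he[order(he$time_h), , drop = FALSE]
    if (nrow(hs) && any(he$time_h <= hs$time_h))
      stop("hd_end precedes hd_start for patient ", demo$id[i],
           call. = FALSE)
    sessions <- if (nrow(hs)) {
      dialysis_session(hs$time_h, he$time_h - hs$time_h, hs$qec_ml_min)
    } else dialysis_session(numeric(0))
    o <- e[e$event == "obs", , drop = FALSE]
    if (nrow(o) && is.unsorted(o$time_h))
      stop("misordered observation times for patient ", demo$id[i],
           call. = FALSE)
    obs <- data.frame(time = o$time_h, conc = o$conc_mg_L)
    list(record = rec, doses = doses, sessions = sessions, obs = obs)
  })
  pk_cohort(patients)
}

#' Write a cohort to the demographics/event-record CSV dialect
#'
#' Inverse of [read_cohort()]; `read_cohort()` of the written files restores
#' the cohort exactly.
#'
#' @param cohort a [pk_cohort()].
#' @param demographics_path,events_path output CSV paths.
#' @return invisibly, a list with the two paths.
#' @export
write_cohort <- function(cohort, demographics_path, events_path) {
  stopifnot(inherits(cohort, "pk_cohort"))
  demo <- do.call(rbind, lapply(cohort, function(p) {
    r <- p$record
    data.frame(id = r$id, age = r$age, weight_kg = r$weight,
               height_cm = r$height, sex = r$sex,
               serum_creat_mmol_L = r$serum_creatinine,
               urine_creat_24h_mmol = r$urine_creatinine_24h,
               serum_urea_mmol_L = r$serum_urea,
               urine_urea_24h_mmol = r$urine_urea_24h)
  }))
  evs <- do.call(rbind, lapply(cohort, function(p) {
    id <- p$record$id
    rows <- list()
    if (nrow(p$doses))
      rows$dose <- data.frame(id = id, time_h = p$doses$start,
                              event = "dose", amount_mg = p$doses$amount,
                              infusion_h = p$doses$infusion_duration,
                              qec_ml_min = NA_real_, conc_mg_L = NA_real_)
    if (nrow(p$sessions)) {
      rows$hs <- data.frame(id = id, time_h = p$sessions$start,
                            event = "hd_start", amount_mg = NA_real_,
                            infusion_h = NA_real_,
                            qec_ml_min = p$sessions$qec_ml_min,
                            conc_mg_L = NA_real_)
      rows$he <- data.frame(id = id,
                            time_h = p$sessions$start + p$sessions$duration,
                            event = "hd_end", amount_mg = NA_real_,
                            infusion_h = NA_real_, qec_ml_min = NA_real_,
                            conc_mg_L = NA_real_)
    }
    if (nrow(p$obs))
      rows$obs <- data.frame(id = id, time_h = p$obs$time, event = "obs",
                             amount_mg = NA_real_, infusion_h = NA_real_,
                             qec_ml_min = NA_real_, conc_mg_L = p$obs$conc)
    do.call(rbind, rows)
  }))
  write.csv(demo, demographics_path, row.names = FALSE, quote = FALSE)
  write.csv(evs, events_path, row.names = FALSE, quote = FALSE)
  invisible(list(demographics = demographics_path, events = events_path))
}
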