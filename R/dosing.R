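# 'A priori' dosing-regimen optimizer: smallest 100-mg-multiple loading and
# maintenance doses whose worst-case AUC24h stays at or above the efficacy
# target (AUC24h/MIC >= 400 with MIC 1 mg/L).  The worst-case window is the
# 24 h preceding a vancomycin administration: it contains the interdialytic
# decay and the steep intradialytic drop of the upcoming session.

#' Dosing regimen specification
#'
#' Describes the simulated "standard patient" and schedule for which a dose
#' is sought: vancomycin is infused during the last `infusion_h` of every
#' dialysis session, sessions repeat every `interval_h`.
#'
#' @param weight body weight, kg.
#' @param qec_ml_min extracorporeal blood flow, mL/min.
#' @param infusion_h infusion duration, h (0.5 or 1 in the reference
#'   tables).
#' @param interval_h dosing/session interval, h (48 or 72).
#' @param session_h dialysis session length, h.
#' @param clcr_ml_min assumed residual creatinine clearance, mL/min.
#' @param target_auc24 AUC24h target, mg*h/L.
#' @param rounding_mg doses are rounded up to a multiple of this step.
#' @param standard_patient covariate convention for the simulated patient:
#'   `"james"` (default) uses a fixed-height standard patient (James
#'   lean-body-mass formula, corrected with ffat 0.4), `"devine"` the
#'   height/sex formula of [lean_body_mass()] at the fixed height, and
#'   `"weight"` sets corrected lean body mass equal to body weight.
#' @param height_cm,sex standard-patient height and sex for the fixed-height
#'   conventions.
#' @param anchor where the 24-h worst-case window ends: at the start of the
#'   upcoming infusion (default; the window then contains the pre-infusion
#'   part of that dialysis session), at the end of the infusion, or at the
#'   end of the session.  Alternatives exist for sensitivity analysis only.
#' @return object of class `regimen_spec`.
#' @export
regimen_spec <- function(weight, qec_ml_min, infusion_h = 1,
                         interval_h = 48, session_h = 4, clcr_ml_min = 4.4,
                         target_auc24 = 400, rounding_mg = 100,
                         standard_patient = c("james", "devine", "weight"),
                         height_cm = 175, sex = "male",
                         anchor = c("infusion_start", "infusion_end",
                                    "session_end")) {
  standard_patient <- match.arg(standard_patient)
  anchor <- match.arg(anchor)
  stopifnot(weight > 0, qec_ml_min >= 0, session_h > 0, interval_h > 0,
            target_auc24 >= 0, rounding_mg > 0, clcr_ml_min >= 0)
  if (infusion_h <= 0 || infusion_h > session_h)
    stop("infusion must fit inside the session", call. = FALSE)
  structure(list(weight = weight, qec_ml_min = qec_ml_min,
                 infusion_h = infusion_h, interval_h = interval_h,
                 session_h = session_h, clcr_ml_min = clcr_ml_min,
                 target_auc24 = target_auc24, rounding_mg = rounding_mg,
                 standard_patient = standard_patient, height_cm = height_cm,
                 sex = sex, anchor = anchor),
            class = "regimen_spec")
}

# corrected lean body mass of the simulated standard patient
standard_lbmc <- function(regimen) {
  switch(regimen$standard_patient,
         weight = regimen$weight,
         devine = lbmc(regimen$weight, regimen$height_cm, regimen$sex),
         james = {
           lbm <- lbm_james(regimen$weight, regimen$height_cm, regimen$sex)
           lbm + 0.4 * (regimen$weight - lbm)
         })
}

#' Standard-patient parameters at the population means
#'
#' @param regimen a [regimen_spec()].
#' @param pop a [population_model()].
#' @return [individual_parameters()] with volumes scaled by the
#'   standard-patient corrected lean body mass.
#' @export
standard_patient_parameters <- function(regimen,
                                        pop = default_population()) {
  m <- pop_means(pop)
  size <- standard_lbmc(regimen)
  individual_parameters(CLm = m[["CLm"]], fr = m[["fr"]],
                        V1 = m[["V1"]] * size, CL12 = m[["CL12"]],
                        V2 = m[["V2"]] * size, Eec = m[["Eec"]],
                        clcr_ml_min = regimen$clcr_ml_min)
}

# sessions 1..n at (k-1)*interval; dose k infused over the last infusion_h
# of session k (amount 0 rows are dropped)
regimen_schedule <- function(regimen, dose_amounts) {
  n <- length(dose_amounts)
  starts <- (seq_len(n) - 1) * regimen$interval_h
  sessions <- dialysis_session(starts, regimen$session_h,
                               regimen$qec_ml_min)
  keep <- dose_amounts > 0
  doses <- dose_event(
    starts[keep] + regimen$session_h - regimen$infusion_h,
    dose_amounts[keep], rep(regimen$infusion_h, sum(keep)))
  list(sessions = sessions, doses = doses)
}

window_end_time <- function(regimen, k) {
  base <- (k - 1) * regimen$interval_h
  switch(regimen$anchor,
         infusion_start = base + regimen$session_h - regimen$infusion_h,
         infusion_end = base + regimen$session_h,
         session_end = base + regimen$session_h)
}

#' Worst-case AUC24h of a dose sequence
#'
#' Simulates `dose_sequence` (one amount per dialysis session, sessions
#' every `interval_h`) and integrates the central concentration over the
#' 24-h window ending at the administration of dose `window_dose` (default:
#' the dose following the sequence).  With the default anchor the window
#' ends at the start of that infusion and includes the pre-infusion part of
#' its dialysis session - the steep intradialytic drop.
#'
#' @param params [individual_parameters()] (absolute volumes), e.g. from
#'   [standard_patient_parameters()].
#' @param regimen a [regimen_spec()].
#' @param dose_sequence mg per session, first session at t = 0.
#' @param window_dose index of the administration whose preceding window is
#'   evaluated.
#' @return AUC over the window, mg*h/L.
#' @export
worst_case_auc24 <- function(params, regimen, dose_sequence,
                             window_dose = length(dose_sequence) + 1) {
  stopifnot(window_dose >= 1)
  we <- window_end_time(regimen, window_dose)
  ws <- we - 24
  if (ws < -1e-9)
    stop("the 24-h window would extend before t = 0", call. = FALSE)
  n_sessions <- max(length(dose_sequence), window_dose)
  amounts <- rep(0, n_sessions)
  amounts[seq_along(dose_sequence)] <- dose_sequence
  # the upcoming administration itself is inside the window only for the
  # infusion_end / session_end anchors
  if (regimen$anchor == "infusion_start" && window_dose <= n_sessions &&
      window_dose > length(dose_sequence)) amounts[window_dose] <- 0
  sched <- regimen_schedule(regimen, amounts)
  horizon <- max(we, (n_sessions - 1) * regimen$interval_h +
                   regimen$session_h) + 1e-6
  course <- simulate_course(params, sched$doses, sched$sessions, horizon)
  auc(course, ws, we)
}

# One dosing interval as an affine map on the (central, peripheral) amounts:
# state_after = M state_before + D * c1.  Returns M (2x2) and c1 (response
# to a unit dose), from which the periodic steady state is
# s* = (I - M)^{-1} D c1 -- exact, no iteration.
interval_map <- function(params, regimen) {
  step <- function(init, dose) {
    sched <- regimen_schedule(regimen, dose)
    course <- simulate_course(params, sched$doses, sched$sessions,
                              regimen$interval_h,
                              output_times = regimen$interval_h,
                              initial_amounts = init)
    c(course$central_amount, course$peripheral_amount)
  }
  M <- cbind(step(c(1, 0), 0), step(c(0, 1), 0))
  list(M = M, c1 = step(c(0, 0), 1))
}

# worst-case window AUC at periodic steady state for maintenance dose D
steady_state_window_auc <- function(params, regimen, dose,
                                    ss_method = c("exact", "iterate"),
                                    iterate_tol = 0.001, max_intervals = 200) {
  ss_method <- match.arg(ss_method)
  if (ss_method == "exact") {
    im <- interval_map(params, regimen)
    sstar <- solve(diag(2) - im$M, dose * im$c1)
    sched <- regimen_schedule(regimen, c(dose, dose))
    we <- window_end_time(regimen, 2)
    course <- simulate_course(params, sched$doses, sched$sessions,
                              regimen$interval_h + regimen$session_h + 1e-6,
                              output_times = we, initial_amounts = sstar)
    return(auc(course, we - 24, we))
  }
  # iterate full intervals until the window AUC settles to < iterate_tol
  state <- c(0, 0)
  prev <- -Inf
  for (k in seq_len(max_intervals)) {
    sched <- regimen_schedule(regimen, c(dose, dose))
    we <- window_end_time(regimen, 2)
    course <- simulate_course(params, sched$doses, sched$sessions,
                              regimen$interval_h + regimen$session_h + 1e-6,
                              output_times = we, initial_amounts = state)
    a <- auc(course, we - 24, we)
    one <- simulate_course(params, sched$doses[1, , drop = FALSE],
                           sched$sessions[1, , drop = FALSE],
                           regimen$interval_h,
                           output_times = regimen$interval_h,
                           initial_amounts = state)
    state <- c(one$central_amount, one$peripheral_amount)
    if (is.finite(prev) && abs(a - prev) < iterate_tol * max(prev, 1e-12))
      return(a)
    prev <- a
  }
  a
}

round_up_dose <- function(target, auc_per_mg, step, max_dose = 10000) {
  if (target <= 0) return(step)
  for (d in seq(step, max_dose, by = step))
    if (d * auc_per_mg >= target) return(d)
  stop("no dose up to ", max_dose, " mg reaches the target", call. = FALSE)
}

#' Minimal loading dose for a dialysis dosing regimen
#'
#' Smallest multiple of `rounding_mg` such that the 24-h window preceding
#' the second administration (the first window containing an intradialytic
#' drop) has AUC at or above the target, for the standard patient at the
#' population means.  Kinetics are linear, so the AUC of the window is
#' proportional to the dose and the first passing multiple is minimal.
#'
#' @param regimen a [regimen_spec()].
#' @param pop a [population_model()].
#' @return loading dose, mg.
#' @examples
#' \donttest{
#' find_loading_dose(regimen_spec(70, 250))  # 1600
#' }
#' @export
find_loading_dose <- function(regimen, pop = default_population()) {
  params <- standard_patient_parameters(regimen, pop)
  base <- worst_case_auc24(params, regimen, 1, window_dose = 2)
  round_up_dose(regimen$target_auc24, base, regimen$rounding_mg)
}

#' Minimal maintenance dose at periodic steady state
#'
#' Smallest multiple of `rounding_mg` such that, when the dose is repeated
#' at every session (uniform `interval_h`), the worst-case 24-h window at
#' periodic steady state has AUC at or above the target.  The steady state
#' is obtained exactly as the fixed point of the one-interval transition
#' map; `ss_method = "iterate"` reproduces the declare-steady-state-when-
#' successive-windows-change-<0.1% procedure instead.
#'
#' @inheritParams find_loading_dose
#' @param ss_method `"exact"` (default) or `"iterate"`.
#' @return maintenance dose, mg.
#' @examples
#' \donttest{
#' find_maintenance_dose(regimen_spec(70, 250))  # 700
#' }
#' @export
find_maintenance_dose <- function(regimen, pop = default_population(),
                                  ss_method = c("exact", "iterate")) {
  ss_method <- match.arg(ss_method)
  params <- standard_patient_parameters(regimen, pop)
  base <- steady_state_window_auc(params, regimen, 1, ss_method)
  round_up_dose(regimen$target_auc24, base, regimen$rounding_mg)
}

#' Loading/maintenance dosing table over a weight x Qec grid
#'
#' Generates the full 'a priori' dosing table: for every combination of
#' body weight, extracorporeal blood flow and infusion duration, the minimal
#' loading dose (window preceding administration 2) and the minimal
#' steady-state maintenance dose.  Deterministic.
#'
#' @param weights body weights, kg.
#' @param qecs extracorporeal blood flows, mL/min.
#' @param infusion_durations infusion lengths, h.
#' @param interval_h dosing interval, h.
#' @param pop a [population_model()].
#' @param ... further arguments to [regimen_spec()].
#' @return data.frame with columns `weight`, `qec_ml_min`, `infusion_h`,
#'   `loading_mg`, `maintenance_mg`, `loading_auc24`, `maintenance_auc24`
#'   (worst-case AUCs achieved at the recommended doses).
#' @export
dosing_table <- function(weights = c(50, 60, 70, 80, 90, 100, 110, 120),
                         qecs = c(200, 250, 300), infusion_durations = 1,
                         interval_h = 48, pop = default_population(), ...) {
  grid <- expand.grid(weight = weights, qec_ml_min = qecs,
                      infusion_h = infusion_durations,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    reg <- regimen_spec(grid$weight[i], grid$qec_ml_min[i],
                        infusion_h = grid$infusion_h[i],
                        interval_h = interval_h, ...)
    params <- standard_patient_parameters(reg, pop)
    lbase <- worst_case_auc24(params, reg, 1, window_dose = 2)
    mbase <- steady_state_window_auc(params, reg, 1)
    ld <- round_up_dose(reg$target_auc24, lbase, reg$rounding_mg)
    md <- round_up_dose(reg$target_auc24, mbase, reg$rounding_mg)
    cbind(grid[i, , drop = FALSE],
          data.frame(loading_mg = ld, maintenance_mg = md,
                     loading_auc24 = ld * lbase,
                     maintenance_auc24 = md * mbase))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a dosing table to the printed wide layout
#'
#' One row per weight; loading-dose columns then maintenance-dose columns,
#' one per (infusion duration, Qec) combination.
#'
#' @param table output of [dosing_table()].
#' @return wide data.frame.
#' @export
dosing_table_wide <- function(table) {
  wts <- sort(unique(table$weight))
  combos <- unique(table[, c("infusion_h", "qec_ml_min")])
  combos <- combos[order(-combos$infusion_h, combos$qec_ml_min), ]
  out <- data.frame(weight_kg = wts)
  for (what in c("loading_mg", "maintenance_mg")) {
    for (j in seq_len(nrow(combos))) {
      sel <- table$infusion_h == combos$infusion_h[j] &
        table$qec_ml_min == combos$qec_ml_min[j]
      col <- table[sel, ][match(wts, table$weight[sel]), what]
      out[[sprintf("%s_inf%gmin_qec%g", sub("_mg", "", what),
                   60 * combos$infusion_h[j], combos$qec_ml_min[j])]] <- col
    }
  }
  out
}
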