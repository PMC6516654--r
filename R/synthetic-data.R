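# Seeded generator of virtual dialysis cohorts with the statistical
# structure the analysis assumes: demographics drawn uniformly within the
# development-cohort ranges, thrice-weekly 4-h sessions with vancomycin
# infused during the last part of each session, sparse sampling around the
# sessions, log-normal inter-individual variability and the
# concentration-dependent assay noise.

#' Cohort design for the synthetic-data generator
#'
#' Defaults describe a development-cohort-like study: n = 17 patients
#' (9 male / 8 female), age 46-85 y, weight 53-95.7 kg, height 145-189 cm,
#' residual creatinine clearance 0.4-16.5 mL/min, dialysis every 48 h for
#' 4 h at Qec 250 mL/min, 1000 mg vancomycin infused during the last hour
#' of each session, and three samples per monitored session (session
#' start, pre-dose during dialysis, 30 min after session end).
#' [table1_default_design()] additionally draws 2-4 monitored sessions and
#' a sparse or rich template per patient, reproducing the development
#' cohort's 2-24 samples-per-patient heterogeneity.
#'
#' @param n_patients number of patients.
#' @param n_male number of male patients (the rest are female).
#' @param age_range,weight_range,height_range,clcr_range demographic ranges
#'   sampled uniformly; `clcr_range` in mL/min.
#' @param n_sessions dialysis sessions per patient.
#' @param interval_h hours between session starts.
#' @param session_h session length, h.
#' @param qec_ml_min extracorporeal blood flow, mL/min.
#' @param dose_mg vancomycin dose per dosed session, mg.
#' @param infusion_h infusion duration, h (infusion ends with the session).
#' @param dosed_sessions indices of sessions in which vancomycin is given.
#' @param sampling `"sparse"`: session start, pre-dose, post-session;
#'   `"rich"`: additionally 1 h and 6 h after each session and a mid-interval
#'   sample; `"table1"` (the default design): each patient is independently
#'   assigned 2 to `n_sessions` monitored sessions and a sparse or rich
#'   template, reproducing the development cohort's wide per-patient
#'   sample-count range.  Identical designs for every patient make the
#'   per-patient likelihood distortions of sparse data line up instead of
#'   averaging out, which real cohorts do not exhibit.
#' @param noise add assay noise to the observations?
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 17, n_male = round(9 * n_patients / 17),
                          age_range = c(46, 85),
                          weight_range = c(53, 95.7),
                          height_range = c(145, 189),
                          clcr_range = c(0.4, 16.5),
                          n_sessions = 3, interval_h = 48, session_h = 4,
                          qec_ml_min = 250, dose_mg = 1000, infusion_h = 1,
                          dosed_sessions = seq_len(n_sessions),
                          sampling = c("sparse", "rich", "table1"),
                          noise = TRUE) {
  sampling <- match.arg(sampling)
  stopifnot(n_patients >= 1, n_male >= 0, n_male <= n_patients,
            n_sessions >= 1, session_h > 0, interval_h > session_h)
  if (infusion_h <= 0 || infusion_h > session_h)
    stop("infusion must fit inside the session", call. = FALSE)
  structure(list(n_patients = n_patients, n_male = n_male,
                 age_range = age_range, weight_range = weight_range,
                 height_range = height_range, clcr_range = clcr_range,
                 n_sessions = n_sessions, interval_h = interval_h,
                 session_h = session_h, qec_ml_min = qec_ml_min,
                 dose_mg = dose_mg, infusion_h = infusion_h,
                 dosed_sessions = dosed_sessions, sampling = sampling,
                 noise = noise),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
table1_default_design <- function() {
  cohort_design(n_sessions = 4, sampling = "table1")
}

# chemistry consistent with a target U*V/P clearance: fix plausible serum
# values and set the 24-h excretions so creatinine and urea clearance both
# equal the target
chemistry_for_clcr <- function(clcr_ml_min) {
  serum_creat <- 0.5  # mmol/L
  serum_urea <- 20    # mmol/L
  list(serum_creatinine = serum_creat,
       urine_creatinine_24h = clcr_ml_min * 1440 / 1000 * serum_creat,
       serum_urea = serum_urea,
       urine_urea_24h = clcr_ml_min * 1440 / 1000 * serum_urea)
}

sampling_times <- function(design, n_sessions = design$n_sessions,
                           rich = identical(design$sampling, "rich")) {
  s0 <- (seq_len(n_sessions) - 1) * design$interval_h
  t <- c(s0,                                     # session start
         s0 + design$session_h - design$infusion_h - 0.1, # just pre-dose
         s0 + design$session_h + 0.5)            # after session end
  if (rich)
    t <- c(t, s0 + design$session_h + 1, s0 + design$session_h + 6,
           s0 + design$interval_h / 2)
  sort(unique(t))
}

#' Generate a synthetic dialysis cohort
#'
#' Samples demographics uniformly within the design ranges, realizes
#' individual parameters from the population model (log-normal IIV),
#' simulates the true concentrations under the dialysis/dosing schedule and
#' adds assay noise `Normal(0, SD_assay(C_true))` truncated at 0.1 mg/L when
#' enabled.  Fully reproducible under a seed.
#'
#' @param design a [cohort_design()].
#' @param pop a [population_model()].
#' @param seed integer seed.
#' @return list with `cohort` (a [pk_cohort()]) and `truth` (data.frame of
#'   the true individual parameters per patient, volumes in absolute L).
#' @export
generate_cohort <- function(design = table1_default_design(),
                            pop = default_population(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(pop, "population_model"))
  set.seed(seed)
  sexes <- rep(c("male", "female"),
               c(design$n_male, design$n_patients - design$n_male))
  patients <- vector("list", design$n_patients)
  truth <- vector("list", design$n_patients)
  # all patient-level randomness is drawn before any observation noise, so
  # the same seed yields the same virtual patients with noise on or off
  for (i in seq_len(design$n_patients)) {
    chem <- chemistry_for_clcr(runif(1, design$clcr_range[1],
                                     design$clcr_range[2]))
    rec <- patient_record(
      sprintf("S%03d", i), age = runif(1, design$age_range[1],
                                       design$age_range[2]),
      weight = runif(1, design$weight_range[1], design$weight_range[2]),
      height = runif(1, design$height_range[1], design$height_range[2]),
      sex = sexes[i], serum_creatinine = chem$serum_creatinine,
      urine_creatinine_24h = chem$urine_creatinine_24h,
      serum_urea = chem$serum_urea, urine_urea_24h = chem$urine_urea_24h)
    params <- realize_individual(pop, rec)
    if (identical(design$sampling, "table1")) {
      n_si <- sample(2:max(2, design$n_sessions), 1)
      times <- sampling_times(design, n_si, rich = runif(1) < 0.45)
      dosed <- seq_len(n_si)
    } else {
      n_si <- design$n_sessions
      times <- sampling_times(design)
      dosed <- design$dosed_sessions
    }
    s0 <- (seq_len(n_si) - 1) * design$interval_h
    sessions <- dialysis_session(s0, design$session_h, design$qec_ml_min)
    ds <- s0[dosed]
    doses <- dose_event(ds + design$session_h - design$infusion_h,
                        rep(design$dose_mg, length(ds)),
                        rep(design$infusion_h, length(ds)))
    ctrue <- predict_conc(params, doses, sessions, times)
    keep <- ctrue > 1e-9  # samples before the first dose carry no signal
    patients[[i]] <- list(record = rec, doses = doses, sessions = sessions,
                          obs = data.frame(time = times[keep],
                                           conc = ctrue[keep]))
    truth[[i]] <- data.frame(id = rec$id, CLm = params$CLm, fr = params$fr,
                             V1 = params$V1, CL12 = params$CL12,
                             V2 = params$V2, Eec = params$Eec,
                             clcr_ml_min = params$clcr_ml_min,
                             lbmc = lbmc(rec$weight, rec$height, rec$sex))
  }
  if (design$noise) {
    for (i in seq_len(design$n_patients)) {
      ctrue <- patients[[i]]$obs$conc
      patients[[i]]$obs$conc <-
        pmax(ctrue + rnorm(length(ctrue), 0,
                           assay_sd(ctrue, pop$assay)), 0.1)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(cohort = pk_cohort(patients), truth = truth)
}
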