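# small builders shared across estimation/evaluation tests

# patient record with chemistry arranged so that the U*V/P residual
# clearance equals clcr_ml_min exactly
std_record <- function(id = "p1", weight = 70, height = 174.2222,
                       sex = "male", clcr_ml_min = 4.4) {
  patient_record(id, age = 65, weight = weight, height = height, sex = sex,
                 serum_creatinine = 0.5,
                 urine_creatinine_24h = clcr_ml_min * 1440 / 1000 * 0.5,
                 serum_urea = 20,
                 urine_urea_24h = clcr_ml_min * 1440 / 1000 * 20)
}

# a population model with every parameter fixed at the packaged means
# (degenerate IIV: realized individuals equal the means exactly)
all_fixed_pop <- function(means = c(CLm = 0.473, fr = 0.1, V1 = 0.278,
                                    CL12 = 9.96, V2 = 0.686, Eec = 0.212)) {
  population_model(lapply(names(means), function(nm)
    parameter_spec(nm, means[[nm]], 0, "fixed")))
}

# one patient with a dialysis schedule, dosed sessions and observations
# simulated from the given per-kg parameter vector (exact, no noise unless
# noise_sd is given)
make_patient <- function(record, theta, n_sessions = 3, interval = 48,
                         session_h = 4, infusion_h = 1, qec = 250,
                         dose = 1000, extra_times = NULL, noise = FALSE) {
  size <- lbmc(record$weight, record$height, record$sex)
  params <- individual_parameters(
    CLm = theta[["CLm"]], fr = theta[["fr"]], V1 = theta[["V1"]] * size,
    CL12 = theta[["CL12"]], V2 = theta[["V2"]] * size,
    Eec = theta[["Eec"]], clcr_ml_min = residual_clcr(record))
  starts <- (seq_len(n_sessions) - 1) * interval
  sessions <- dialysis_session(starts, session_h, qec)
  doses <- dose_event(starts + session_h - infusion_h,
                      rep(dose, n_sessions), rep(infusion_h, n_sessions))
  times <- sort(unique(c(starts + session_h - infusion_h - 0.1,
                         starts + session_h + 0.5, starts[-1], extra_times)))
  conc <- predict_conc(params, doses, sessions, times)
  keep <- conc > 1e-9
  conc <- conc[keep]
  if (noise) conc <- pmax(conc + rnorm(length(conc), 0, assay_sd(conc)), 0.1)
  list(record = record, doses = doses, sessions = sessions,
       obs = data.frame(time = times[keep], conc = conc))
}
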