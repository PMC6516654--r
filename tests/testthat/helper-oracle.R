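# Independent fixed-step RK4 oracle for the piecewise-constant
# two-compartment system.  Kept deliberately naive (no closed forms, no
# shared code with the package internals): it integrates the ODE
#   dA1/dt = r(t) - (cl(t) + CL12) A1/V1 + CL12 A2/V2
#   dA2/dt =        CL12 A1/V1          - CL12 A2/V2
# with steps that respect every event discontinuity.  Step size h = 0.005 h
# gives global error far below the 1e-6 relative comparison tolerance for
# the rate constants arising here (verified by halving h).

oracle_conc <- function(params, doses, sessions, times, h = 0.005) {
  times <- sort(unique(times))
  horizon <- max(times)
  cl_body <- params$CLm + params$fr * params$clcr_ml_min * 0.06
  rate_at <- function(t) {
    r <- 0
    if (!is.null(doses) && nrow(doses)) {
      act <- t > doses$start & t < doses$start + doses$infusion_duration
      r <- sum(doses$amount[act] / doses$infusion_duration[act])
    }
    r
  }
  cl_at <- function(t) {
    cl <- cl_body
    if (!is.null(sessions) && nrow(sessions)) {
      act <- t > sessions$start & t < sessions$start + sessions$duration
      if (any(act))
        cl <- cl + sessions$qec_ml_min[act][1] * 0.06 * params$Eec
    }
    cl
  }
  cuts <- sort(unique(c(0, horizon, times,
                        if (!is.null(doses)) c(doses$start,
                          doses$start + doses$infusion_duration),
                        if (!is.null(sessions)) c(sessions$start,
                          sessions$start + sessions$duration))))
  cuts <- cuts[cuts >= 0 & cuts <= horizon]
  A <- c(0, 0)
  out <- numeric(length(times))
  deriv <- function(A, r, cl) {
    c(r - (cl + params$CL12) * A[1] / params$V1 +
        params$CL12 * A[2] / params$V2,
      params$CL12 * A[1] / params$V1 - params$CL12 * A[2] / params$V2)
  }
  for (i in seq_len(length(cuts) - 1)) {
    t0 <- cuts[i]; t1 <- cuts[i + 1]
    mid <- (t0 + t1) / 2
    r <- rate_at(mid); cl <- cl_at(mid)
    n <- max(1L, ceiling((t1 - t0) / h))
    dt <- (t1 - t0) / n
    for (s in seq_len(n)) {
      k1 <- deriv(A, r, cl)
      k2 <- deriv(A + dt / 2 * k1, r, cl)
      k3 <- deriv(A + dt / 2 * k2, r, cl)
      k4 <- deriv(A + dt * k3, r, cl)
      A <- A + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out[hit] <- A[1] / params$V1
  }
  out
}

# random but physiologically shaped simulation scenario
random_scenario <- function() {
  params <- individual_parameters(
    CLm = runif(1, 0.1, 2), fr = runif(1, 0, 0.3),
    V1 = runif(1, 5, 40), CL12 = runif(1, 0, 20),
    V2 = runif(1, 10, 100), Eec = runif(1, 0.05, 0.5),
    clcr_ml_min = runif(1, 0, 20))
  horizon <- runif(1, 60, 120)
  n_s <- sample(0:3, 1)
  sessions <- if (n_s > 0) {
    starts <- sort(runif(n_s, 0, horizon - 6))
    starts <- starts[c(TRUE, diff(starts) > 6)]
    dialysis_session(starts, runif(length(starts), 2, 5),
                     runif(length(starts), 150, 350))
  } else NULL
  n_d <- sample(1:3, 1)
  dstart <- runif(n_d, 0, horizon - 3)
  doses <- dose_event(dstart, runif(n_d, 250, 2000), runif(n_d, 0.25, 2))
  times <- sort(runif(12, 0.5, horizon))
  list(params = params, doses = doses, sessions = sessions,
       horizon = horizon, times = times)
}
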