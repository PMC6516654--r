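# proportional assay model: weights scale with concentration, so doubling
# doses and observations leaves the weighted objective shape unchanged
prop_assay <- assay_error_model(1e-6, 0.1, 0)

test_that("MAP fit recovers a patient generated at the population means", {
  truth <- c(CLm = 0.473, fr = 0.1, V1 = 0.278, CL12 = 9.96, V2 = 0.686,
             Eec = 0.212)
  pat <- make_patient(std_record(), truth, n_sessions = 4,
                      extra_times = c(6, 12, 24, 30, 54, 60, 72, 78, 102))
  fit <- map_fit(pat, default_population())
  expect_true(fit$converged)
  # residuals vanish at the truth, so the optimum sits essentially on it
  expect_lt(fit$wss, 0.05)
  expect_equal(unname(fit$theta[c("CLm", "V1", "V2", "Eec")]),
               unname(truth[c("CLm", "V1", "V2", "Eec")]), tolerance = 0.05)
})

test_that("with uninformative data the MAP estimate collapses to the prior center", {
  pat <- make_patient(std_record(),
                      c(CLm = 0.9, fr = 0.1, V1 = 0.5, CL12 = 9.96,
                        V2 = 0.4, Eec = 0.1), n_sessions = 1)
  pat$obs <- pat$obs[1, , drop = FALSE]  # single observation
  fit <- map_fit(pat, default_population(), gamma = 1e4)  # huge assay SD
  pop <- default_population()
  centers <- vapply(c("CLm", "V1", "V2", "Eec"), function(nm) {
    s <- pop$specs[[nm]]
    s$mean / sqrt(1 + (s$sd / s$mean)^2)  # log-normal median
  }, numeric(1))
  expect_equal(unname(fit$theta[names(centers)]), unname(centers),
               tolerance = 0.01)
})

test_that("MAP recovers shifted parameters from rich low-noise data", {
  truth <- c(CLm = 0.6, fr = 0.1, V1 = 0.36, CL12 = 9.96, V2 = 0.55,
             Eec = 0.28)
  pat <- make_patient(std_record(), truth, n_sessions = 4,
                      extra_times = c(6, 12, 24, 30, 54, 60, 72, 78, 102))
  fit <- map_fit(pat, default_population(), gamma = 0.01)  # noise SD -> 0
  expect_equal(unname(fit$theta[c("CLm", "V1", "V2", "Eec")]),
               unname(truth[c("CLm", "V1", "V2", "Eec")]), tolerance = 0.05)
})

test_that("all-fixed populations short-circuit ITSB in one cycle", {
  cohort <- pk_cohort(lapply(1:3, function(i)
    make_patient(std_record(sprintf("p%d", i), weight = 60 + 5 * i),
                 c(CLm = 0.473, fr = 0.1, V1 = 0.278, CL12 = 9.96,
                   V2 = 0.686, Eec = 0.212))))
  fit <- itsb(cohort, all_fixed_pop())
  expect_equal(fit$n_iterations, 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["CLm", ]), rep(0.473, 3))
  expect_error(eta_shrinkage(fit, "CLm"), "bayesian")
})

test_that("doubling doses and concentrations leaves estimates unchanged", {
  set.seed(11)
  truth <- c(CLm = 0.6, fr = 0.1, V1 = 0.31, CL12 = 9.96, V2 = 0.62,
             Eec = 0.25)
  pop <- population_model(default_population()$specs, prop_assay)
  p1 <- make_patient(std_record(), truth, n_sessions = 3, dose = 1000)
  p2 <- p1
  p2$doses$amount <- 2 * p2$doses$amount
  p2$obs$conc <- 2 * p2$obs$conc
  f1 <- map_fit(p1, pop)
  f2 <- map_fit(p2, pop)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
})

test_that("AIC and WSS/df follow their definitions on a real fit", {
  set.seed(3)
  gen <- generate_cohort(cohort_design(n_patients = 6), seed = 3)
  fit <- itsb(gen$cohort, default_population(), max_iter = 15, tol = 1e-3)
  expect_equal(fit$p, 2 * 4)  # mean and SD of the four bayesian parameters
  expect_equal(fit$df, fit$n_obs - fit$p)
  expect_equal(aic(fit), fit$n_obs * log(fit$wss / fit$n_obs) + 2 * fit$p)
  expect_equal(wss_per_df(fit), fit$wss / fit$df)
  # p counts only bayesian-mode parameters
  fit0 <- itsb(gen$cohort, all_fixed_pop())
  expect_equal(fit0$p, 0)
  expect_equal(fit0$df, fit0$n_obs)
})

test_that("eta-shrinkage implements 1 - SD_ind/SD_pop on the log scale", {
  # hand-built fit object with known spreads
  mk_fit <- function(log_sd_ind, cv_pop = 0.3) {
    sigma <- sqrt(log(1 + cv_pop^2))
    mean_ <- 0.2
    ests <- exp(log(mean_) + log_sd_ind * scale(seq_len(8))[, 1])
    structure(list(
      final_pop = population_model(list(
        parameter_spec("CLm", 0.473, 0.271, "bayesian"),
        parameter_spec("fr", 0.1, 0, "fixed"),
        parameter_spec("V1", 0.278, 0.092, "bayesian"),
        parameter_spec("CL12", 9.96, 0, "fixed"),
        parameter_spec("V2", 0.686, 0.335, "bayesian"),
        parameter_spec("Eec", mean_, mean_ * cv_pop, "bayesian"))),
      estimates = matrix(rep(ests, each = 6), 6,
                         dimnames = list(c("CLm", "fr", "V1", "CL12", "V2",
                                           "Eec"), NULL))),
      class = "itsb_fit")
  }
  sigma <- sqrt(log(1 + 0.3^2))
  expect_equal(eta_shrinkage(mk_fit(0), "Eec"), 1)       # identical estimates
  expect_equal(eta_shrinkage(mk_fit(sigma), "Eec"), 0, tolerance = 1e-9)
  expect_equal(eta_shrinkage(mk_fit(sigma / 2), "Eec"), 0.5,
               tolerance = 1e-9)
})

test_that("shrinkage grows as per-patient sampling gets sparser", {
  pop <- default_population()
  sparse <- generate_cohort(cohort_design(n_patients = 12, n_sessions = 2),
                            seed = 17)
  rich <- generate_cohort(cohort_design(n_patients = 12, n_sessions = 4,
                                        sampling = "rich"), seed = 17)
  fs <- itsb(sparse$cohort, pop, max_iter = 25, tol = 1e-3)
  fr <- itsb(rich$cohort, pop, max_iter = 25, tol = 1e-3)
  shr <- function(f) mean(vapply(c("CLm", "V1", "V2", "Eec"),
                                 function(nm) eta_shrinkage(f, nm),
                                 numeric(1)))
  expect_gt(shr(fs), shr(fr))
})

test_that("stepwise search stays all-fixed when the literature model is the truth", {
  truth <- c(CLm = 0.473, fr = 0.1, V1 = 0.278, CL12 = 9.96, V2 = 0.686,
             Eec = 0.212)
  cohort <- pk_cohort(lapply(1:6, function(i)
    make_patient(std_record(sprintf("p%d", i), weight = 55 + 5 * i), truth)))
  tr <- stepwise_search(cohort, all_fixed_pop(truth), max_iter = 10,
                        tol = 1e-3)
  expect_equal(sum(tr$accepted), 1)  # only the starting row
  expect_equal(pop_modes(attr(tr, "final_pop")),
               setNames(rep("fixed", 6),
                        c("CLm", "fr", "V1", "CL12", "V2", "Eec")))
})

test_that("stepwise search first frees the parameter that truly varies", {
  set.seed(29)
  gen_pop <- population_model(list(
    parameter_spec("CLm", 0.473, 0.5 * 0.473, "bayesian"),
    parameter_spec("fr", 0.1, 0, "fixed"),
    parameter_spec("V1", 0.278, 0, "fixed"),
    parameter_spec("CL12", 9.96, 0, "fixed"),
    parameter_spec("V2", 0.686, 0, "fixed"),
    parameter_spec("Eec", 0.212, 0, "fixed")))
  gen <- generate_cohort(cohort_design(n_patients = 8, n_sessions = 3,
                                       sampling = "rich"),
                         pop = gen_pop, seed = 29)
  tr <- stepwise_search(gen$cohort, all_fixed_pop(), max_iter = 10,
                        tol = 1e-3)
  first <- tr[tr$accepted & tr$step == 1, ]
  expect_equal(nrow(first), 1)
  expect_equal(first$parameter, "CLm")
  # accepted AICs decrease by at least the threshold at every step
  acc <- tr$aic[tr$accepted]
  expect_true(all(diff(acc) <= -2))
})

test_that("bootstrap collapses for a single replicate and for identical patients", {
  truth <- c(CLm = 0.473, fr = 0.1, V1 = 0.278, CL12 = 9.96, V2 = 0.686,
             Eec = 0.212)
  base <- make_patient(std_record("a"), truth, n_sessions = 2)
  cohort <- pk_cohort(lapply(c("a", "b", "c"), function(id) {
    p <- base; p$record$id <- id; p
  }))
  b1 <- bootstrap_pop(cohort, default_population(), n_reps = 1, seed = 4,
                      max_iter = 5, tol = 1e-2)
  expect_equal(b1$lower, b1$upper)
  b2 <- bootstrap_pop(cohort, default_population(), n_reps = 4, seed = 4,
                      max_iter = 5, tol = 1e-2)
  expect_equal(b2$lower, b2$upper, tolerance = 1e-6)
  expect_equal(attr(b2, "n_failed"), 0)
  # CI brackets the full-cohort estimate for every quantity
  expect_true(all(b2$lower <= b2$estimate + 1e-9 &
                    b2$estimate <= b2$upper + 1e-9))
})
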