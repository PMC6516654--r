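test_that("corrected lean body mass follows the height/sex formula", {
  # BW = LBM fixed point: the fat-correction term vanishes
  expect_equal(lbmc(50, 152, "male"), 50)
  expect_equal(lbmc(70, 175, "male"), 70.42)
  expect_equal(lbmc(60, 160, "female"), 55.62)
  expect_error(lbmc(-1, 170, "male"), "weight")
  expect_error(lbmc(70, 90, "male"), "height")
  expect_error(lbmc(70, 260, "male"), "height")
})

test_that("residual creatinine clearance is the mean U*V/P of creatinine and urea", {
  expect_equal(residual_clcr(0.5, 10, 20, 300), 12.1528, tolerance = 1e-4)
  expect_equal(residual_clcr(0.5, 0, 20, 0), 0)
  # linear in the urinary excretions
  expect_equal(residual_clcr(0.5, 20, 20, 600),
               2 * residual_clcr(0.5, 10, 20, 300))
  expect_error(residual_clcr(0, 10, 20, 300), "serum")
  rec <- std_record(clcr_ml_min = 4.4)
  expect_equal(residual_clcr(rec), 4.4)
})

test_that("total clearance adds the extracorporeal term only on dialysis", {
  p <- individual_parameters(CLm = 0.473, fr = 0.1, V1 = 19.46,
                             CL12 = 9.96, V2 = 48.02, Eec = 0.212,
                             clcr_ml_min = 4.4)
  expect_equal(total_clearance(p, FALSE), 0.4994)
  expect_equal(total_clearance(p, TRUE, 250), 3.6794)
  p0 <- individual_parameters(CLm = 0.473, fr = 0.1, V1 = 19.46,
                              CL12 = 9.96, V2 = 48.02, Eec = 0,
                              clcr_ml_min = 4.4)
  expect_equal(total_clearance(p0, TRUE, 250), total_clearance(p0, FALSE))
  expect_error(total_clearance(p, TRUE, -5), "Qec")
})

test_that("parameter and event constructors enforce their invariants", {
  expect_error(individual_parameters(0.5, 1.2, 20, 10, 50, 0.2), "fr")
  expect_error(individual_parameters(0.5, 0.1, 20, 10, 50, 1.4), "Eec")
  expect_error(individual_parameters(-0.5, 0.1, 20, 10, 50, 0.2), "finite")
  expect_error(dose_event(-1, 500, 1), "start")
  expect_error(dose_event(0, -500, 1), "amounts")
  expect_error(dose_event(0, 500, 0), "infusion_duration")
  expect_error(dialysis_session(c(0, 2), 4, 250), "overlap")
})

test_that("simulator reproduces the one-compartment closed form", {
  p <- individual_parameters(CLm = 1, fr = 0, V1 = 20, CL12 = 0, V2 = 1,
                             Eec = 0)
  tt <- c(0, 5, 10, 20)
  # true bolus via the initial state: C(t) = 50 exp(-0.05 t)
  s <- simulate_course(p, NULL, NULL, 20, output_times = tt,
                       initial_amounts = c(1000, 0))
  expect_equal(s$conc, 50 * exp(-0.05 * tt), tolerance = 1e-9)
  # AUC(0, infinity) = dose / CL for any single dose at constant clearance
  s2 <- simulate_course(p, dose_event(0, 1000, 0.5), NULL, 600)
  expect_equal(auc(s2, 0, 600), 1000 / 1, tolerance = 1e-6)
  # explicit closed-form window: C0 = 50, k = 0.05, window 0-20 h
  expect_equal(auc(s, 0, 20), 50 / 0.05 * (1 - exp(-1)), tolerance = 1e-9)
})

test_that("auc is additive and validates its window", {
  p <- individual_parameters(CLm = 0.8, fr = 0.1, V1 = 15, CL12 = 8,
                             V2 = 40, Eec = 0.2, clcr_ml_min = 5)
  s <- simulate_course(p, dose_event(2, 800, 1),
                       dialysis_session(c(0, 48), 4, 250), 80)
  expect_equal(auc(s, 5, 30) + auc(s, 30, 70), auc(s, 5, 70),
               tolerance = 1e-9)
  expect_error(auc(s, 30, 30), "window_end")
  expect_error(auc(s, 10, 90), "horizon")
})

test_that("simulation matches the independent RK4 oracle and conserves mass", {
  set.seed(421)
  for (i in 1:8) {
    sc <- random_scenario()
    course <- simulate_course(sc$params, sc$doses, sc$sessions, sc$horizon,
                              output_times = sc$times)
    ref <- oracle_conc(sc$params, sc$doses, sc$sessions, sc$times)
    expect_equal(course$conc, ref, tolerance = 1e-6)
    expect_true(all(course$conc >= 0))
    # mass balance at every reported time
    balance <- course$central_amount + course$peripheral_amount +
      course$cumulative_eliminated + course$cumulative_dialyzed
    expect_equal(balance, course$cumulative_infused,
                 tolerance = 1e-6)
  }
})

test_that("no dialyzed mass accumulates without sessions and refinement changes nothing", {
  p <- individual_parameters(CLm = 0.5, fr = 0.1, V1 = 20, CL12 = 10,
                             V2 = 50, Eec = 0.3, clcr_ml_min = 4.4)
  d <- dose_event(1, 1000, 1)
  s <- simulate_course(p, d, NULL, 48)
  expect_true(all(s$cumulative_dialyzed == 0))
  # inserting extra output times does not perturb the solution
  tt <- c(4, 12, 36)
  coarse <- simulate_course(p, d, dialysis_session(0, 4, 250), 48,
                            output_times = tt)
  fine <- simulate_course(p, d, dialysis_session(0, 4, 250), 48,
                          output_times = sort(c(tt, runif(20, 0, 48))))
  expect_equal(fine$conc[match(tt, fine$time)], coarse$conc,
               tolerance = 1e-12)
})

test_that("degenerate rate structures are handled exactly", {
  # CL12 = 0 and CL = 0: pure accumulation during infusion
  p <- individual_parameters(CLm = 0, fr = 0, V1 = 10, CL12 = 0, V2 = 5,
                             Eec = 0)
  s <- simulate_course(p, dose_event(0, 600, 2), NULL, 4,
                       output_times = c(1, 2, 4))
  expect_equal(s$central_amount, c(300, 600, 600), tolerance = 1e-9)
  # V2 effectively absent (CL12 = 0) leaves the peripheral amount at zero
  expect_true(all(s$peripheral_amount == 0))
})
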