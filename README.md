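# vanchd

Population pharmacokinetics and dosing of vancomycin in patients on
intermittent hemodialysis and online hemodiafiltration.

Dialysis patients get vancomycin during the last 30–60 minutes of their
dialysis sessions, and the dialyzer removes a substantial fraction of
every dose.  Dosing them well means answering a quantitative question:
what loading and maintenance doses keep the 24-hour area under the
concentration–time curve at or above 400 mg·h/L (the AUC24h/MIC target
at MIC 1 mg/L) in the *worst-case* 24 hours — the window ending at the
next administration, which contains the longest interdialytic decay and
the steep intradialytic drop?  This package implements the full
workflow behind that answer for clinical pharmacologists and
pharmacometricians:

* a two-compartment disposition model with a switchable extracorporeal
  clearance term,

  CL(t) = CLm + fr·CLcr + Qec·Eec·[dialysis running],

  solved piecewise-analytically (no step-size error, exact AUC and mass
  balance), with central/peripheral volumes scaling on corrected lean
  body mass (LBMc);
* iterative two-stage Bayesian (ITSB) population estimation with a
  concentration-dependent assay-error model
  (SD(C) = 1.3842 + 0.0626·C + 0.0018·C²), an AIC-guided
  Fixed/FPB/Bayesian stepwise parameter-setting search, η-shrinkage and
  patient-level bootstrap;
* external predictive-performance evaluation: population vs individual
  predictions, MDPE/MDAPE with bootstrap confidence intervals, weighted
  residuals;
* the worst-case-window dose optimizer that generates loading and
  maintenance dose tables over body weight × extracorporeal blood flow
  grids for 48-h and 72-h schedules;
* a seeded synthetic-cohort generator emulating a 17-patient
  hemodiafiltration development cohort, so every stage is testable
  without patient data.

The packaged default population model is: CLm 0.473 (SD 0.271) L/h,
fr 0.100 (fixed), V1 0.278 (0.092) L/kgLBMc, CL12 9.96 L/h (fixed),
V2 0.686 (0.335) L/kgLBMc, Eec 0.212 (0.069), log-normal
inter-individual variability.

## Worked example

Dose a 70-kg standard patient dialyzed 4 h every 48 h at an
extracorporeal blood flow of 250 mL/min, vancomycin infused during the
last hour of each session:

```r
library(vanchd)

reg <- regimen_spec(weight = 70, qec_ml_min = 250,
                    infusion_h = 1, interval_h = 48)
find_loading_dose(reg)
#> [1] 1600
find_maintenance_dose(reg)
#> [1] 700

params <- standard_patient_parameters(reg)
worst_case_auc24(params, reg, 1600, window_dose = 2)
#> [1] 417.4296
```

1600 mg up front makes the 24 h before the second administration
integrate to 417 mg·h/L (target 400), and 700 mg at every subsequent
session holds the steady-state worst-case window above target.
`dosing_table()` expands this over the full weight/Qec/infusion grid.

Fitting and evaluating on a synthetic cohort:

```r
gen <- generate_cohort(table1_default_design(), seed = 42)
fit <- itsb(gen$cohort, default_population())
fit
#> <itsb_fit> 17 patients, 167 obs; WSS 148.865, df 159, AIC -3.20, converged after 63 iterations
#> <population_model> log-normal IIV
#>   CLm   mean 0.7103  sd 0.342   bayesian
#>   fr    mean 0.1     sd 0       fixed
#>   V1    mean 0.3421  sd 0.1463  bayesian
#>   CL12  mean 9.96    sd 0       fixed
#>   V2    mean 0.7056  sd 0.6554  bayesian
#>   Eec   mean 0.1937  sd 0.09255 bayesian
#>   assay SD(C) = 1.3842 + 0.0626 C + 0.0018 C^2

ev <- evaluate_model(gen$cohort, fit$final_pop, n_reps = 2000, seed = 1)
sprintf("MDPE %.1f%%  MDAPE %.1f%%", ev$mdpe, ev$mdape)
#> [1] "MDPE 3.1%  MDAPE 12.6%"
```

MDPE is the median relative prediction error (bias) and MDAPE its
absolute counterpart (precision) of the individual Bayesian predictions;
a 17-patient sparse cohort recovers the generating kinetics to within
the scatter expected at this size.

A thin command-line launcher covering the same workflow
(`synth`, `simulate`, `fit`, `evaluate`, `dose-table`, `dose`) ships at
`inst/scripts/vanchd`.

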