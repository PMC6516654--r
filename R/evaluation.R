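# External predictive-performance evaluation: population vs individual
# predictions, MDPE/MDAPE with bootstrap confidence intervals, weighted
# residuals.

#' Population and individual predictions for a cohort
#'
#' `predict_population()` simulates every patient at the population means
#' (volumes scaled by the patient's corrected lean body mass, residual CLcr
#' and dialysis/dose schedule taken from the record) without any fitting, so
#' the predictions are independent of the observed concentrations.
#' `predict_individual()` first computes one MAP fit per patient against the
#' fixed population prior (one ITSB cycle, population untouched) and
#' simulates at the individual estimates.
#'
#' @param cohort a [pk_cohort()].
#' @param pop a [population_model()].
#' @param gamma residual-error inflation factor (individual mode only).
#' @return data.frame of prediction pairs: `id`, `time`, `observed`,
#'   `predicted`, `mode`.
#' @export
predict_population <- function(cohort, pop = default_population()) {
  stopifnot(inherits(cohort, "pk_cohort"))
  out <- do.call(rbind, lapply(cohort, function(p) {
    prep <- prep_patient(p)
    data.frame(id = p$record$id, time = p$obs$time, observed = p$obs$conc,
               predicted = prep_predict(prep, pop_means(pop)),
               mode = "population")
  }))
  rownames(out) <- NULL
  out
}

#' @rdname predict_population
#' @export
predict_individual <- function(cohort, pop = default_population(),
                               gamma = 1) {
  stopifnot(inherits(cohort, "pk_cohort"))
  out <- do.call(rbind, lapply(cohort, function(p) {
    fit <- map_fit(p, pop, gamma)
    data.frame(id = p$record$id, time = fit$predictions$time,
               observed = fit$predictions$observed,
               predicted = fit$predictions$predicted, mode = "individual")
  }))
  rownames(out) <- NULL
  out
}

check_pairs <- function(pairs) {
  need <- c("observed", "predicted")
  if (!all(need %in% names(pairs)))
    stop("pairs need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(pairs) < 1) stop("no prediction pairs", call. = FALSE)
  if (any(pairs$observed <= 0))
    stop("observed concentrations must be positive", call. = FALSE)
  invisible(pairs)
}

#' Median (absolute) prediction error
#'
#' Bias and precision of model predictions:
#' \deqn{MDPE = median\left(\frac{C_{pred} - C_{obs}}{C_{obs}}\right), \quad
#'       MDAPE = median\left(\left|\frac{C_{pred} - C_{obs}}{C_{obs}}\right|\right)}
#' both reported in percent.  The median of an even count is the midpoint of
#' the central pair.
#'
#' @param pairs data.frame with columns `observed` and `predicted` (e.g.
#'   from [predict_individual()], or a two-column table of pre-computed
#'   predictions).
#' @return percent.
#' @examples
#' mdpe(data.frame(observed = c(10, 10, 10), predicted = c(10, 12, 8)))  # 0
#' mdape(data.frame(observed = c(10, 10, 10), predicted = c(10, 12, 8))) # 20
#' @export
mdpe <- function(pairs) {
  check_pairs(pairs)
  100 * median((pairs$predicted - pairs$observed) / pairs$observed)
}

#' @rdname mdpe
#' @export
mdape <- function(pairs) {
  check_pairs(pairs)
  100 * median(abs(pairs$predicted - pairs$observed) / pairs$observed)
}

#' Bootstrap confidence intervals for MDPE and MDAPE
#'
#' Percentile intervals from `n_reps` resamples.  The resampling unit is the
#' patient by default (all of a patient's pairs enter or leave together);
#' `unit = "observation"` resamples individual pairs instead.
#'
#' @param pairs prediction pairs with an `id` column (patient mode).
#' @param n_reps replicates (10000 in the reference workflow).
#' @param seed integer seed.
#' @param unit `"patient"` or `"observation"`.
#' @param level confidence level.
#' @return data.frame with rows MDPE and MDAPE: `estimate`, `lower`,
#'   `upper`.
#' @export
bootstrap_mdpe <- function(pairs, n_reps = 10000, seed = 1,
                           unit = c("patient", "observation"),
                           level = 0.95) {
  check_pairs(pairs)
  unit <- match.arg(unit)
  if (unit == "patient" && !"id" %in% names(pairs))
    stop("patient-level bootstrap needs an 'id' column", call. = FALSE)
  set.seed(seed)
  pe <- 100 * (pairs$predicted - pairs$observed) / pairs$observed
  stat <- function(x) c(mdpe = median(x), mdape = median(abs(x)))
  reps <- matrix(NA_real_, n_reps, 2)
  if (unit == "patient") {
    ids <- unique(pairs$id)
    by_id <- split(pe, pairs$id)[as.character(ids)]
    for (r in seq_len(n_reps))
      reps[r, ] <- stat(unlist(by_id[sample.int(length(ids),
                                                replace = TRUE)],
                               use.names = FALSE))
  } else {
    n <- length(pe)
    for (r in seq_len(n_reps))
      reps[r, ] <- stat(pe[sample.int(n, replace = TRUE)])
  }
  a <- (1 - level) / 2
  out <- data.frame(
    statistic = c("MDPE", "MDAPE"),
    estimate = stat(pe),
    lower = apply(reps, 2, quantile, a),
    upper = apply(reps, 2, quantile, 1 - a))
  rownames(out) <- NULL
  out
}

#' Assay-weighted residuals
#'
#' `(observed - predicted) / SD_assay(observed)` for each pair; positive
#' when the model under-predicts.  Returned with the predictions so the
#' standard residuals-vs-predicted diagnostic can be plotted directly.
#'
#' @param pairs prediction pairs.
#' @param assay an [assay_error_model()].
#' @param gamma residual-error inflation factor.
#' @return `pairs` with an extra `weighted_residual` column.
#' @export
weighted_residuals <- function(pairs, assay = assay_error_model(),
                               gamma = 1) {
  check_pairs(pairs)
  pairs$weighted_residual <-
    (pairs$observed - pairs$predicted) / assay_sd(pairs$observed, assay,
                                                  gamma)
  pairs
}

#' Evaluate predictive performance of a model on a cohort
#'
#' Convenience wrapper: computes population and individual prediction pairs,
#' MDPE/MDAPE (individual mode, the external-evaluation headline statistics)
#' with bootstrap CIs, and the weighted-residual table.  A pre-computed
#' two-column `observed`/`predicted` table can be supplied instead of a
#' cohort via [mdpe()], [mdape()] and [bootstrap_mdpe()] directly.
#'
#' @param cohort a [pk_cohort()].
#' @param pop a [population_model()].
#' @param n_reps bootstrap replicates.
#' @param seed integer seed.
#' @return list with `pairs` (both modes), `mdpe`, `mdape`, `ci`
#'   (bootstrap table), `residuals`.
#' @export
evaluate_model <- function(cohort, pop = default_population(),
                           n_reps = 10000, seed = 1) {
  ind <- predict_individual(cohort, pop)
  popp <- predict_population(cohort, pop)
  ci <- bootstrap_mdpe(ind, n_reps = n_reps, seed = seed)
  list(pairs = rbind(popp, ind),
       mdpe = mdpe(ind), mdape = mdape(ind), ci = ci,
       residuals = weighted_residuals(rbind(popp, ind), pop$assay))
}
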