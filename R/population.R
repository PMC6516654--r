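PK_PARAM_NAMES <- c("CLm", "fr", "V1", "CL12", "V2", "Eec")
PK_PARAM_MODES <- c("bayesian", "fpb", "fixed")

#' Population parameter specification
#'
#' One parameter of the population model: natural-scale mean and standard
#' deviation of a log-normal inter-individual distribution, plus the
#' estimation mode used by the ITSB machinery:
#' \describe{
#'   \item{bayesian}{individually estimated; population mean and SD updated
#'     between ITSB cycles.}
#'   \item{fpb}{"fixed population Bayesian": individually estimated against a
#'     fixed prior; the population mean/SD are never updated.}
#'   \item{fixed}{a constant; never estimated, SD must be 0.}
#' }
#' Volumes (`V1`, `V2`) are expressed per kg of corrected lean body mass
#' (L/kgLBMc) and are scaled to absolute volumes when an individual is
#' realized.
#'
#' @param name one of `"CLm"`, `"fr"`, `"V1"`, `"CL12"`, `"V2"`, `"Eec"`.
#' @param mean natural-scale mean (L/h, L/kgLBMc, or dimensionless).
#' @param sd natural-scale SD; 0 if and only if `mode = "fixed"`.
#' @param mode estimation mode.
#' @return object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, mean, sd = 0,
                           mode = c("bayesian", "fpb", "fixed")) {
  name <- match.arg(name, PK_PARAM_NAMES)
  mode <- match.arg(mode)
  if (mean < 0) stop("parameter mean must be >= 0", call. = FALSE)
  if (sd < 0) stop("parameter sd must be >= 0", call. = FALSE)
  if (mode == "fixed" && sd != 0)
    stop("a fixed parameter must have sd = 0", call. = FALSE)
  if (mode != "fixed" && sd == 0)
    stop("a ", mode, " parameter needs sd > 0", call. = FALSE)
  structure(list(name = name, mean = mean, sd = sd, mode = mode),
            class = "parameter_spec")
}

#' Assay error model: concentration-dependent measurement SD
#'
#' Second-degree polynomial `SD(C) = c0 + c1*C + c2*C^2` describing the
#' standard deviation of the concentration assay; used as the weighting of
#' residuals throughout estimation and evaluation.  The packaged default is
#' the immunoassay polynomial `1.3842 + 0.0626 C + 0.0018 C^2`.
#'
#' @param c0,c1,c2 polynomial coefficients (mg/L scale).
#' @return object of class `assay_error_model`.
#' @export
assay_error_model <- function(c0 = 1.3842, c1 = 0.0626, c2 = 0.0018) {
  m <- structure(list(c0 = c0, c1 = c1, c2 = c2), class = "assay_error_model")
  test <- assay_sd(c(0, 1, 10, 100, 1000), m)
  if (any(test <= 0))
    stop("assay SD must be positive for all C >= 0", call. = FALSE)
  m
}

#' Assay standard deviation at a concentration
#'
#' @param conc concentration(s), mg/L (>= 0).
#' @param assay an [assay_error_model()]; packaged default if omitted.
#' @param gamma optional scalar multiplying the polynomial (residual-error
#'   inflation factor), default 1.
#' @return SD(s), mg/L.
#' @examples
#' assay_sd(c(0, 10, 50))  # 1.3842 2.1902 9.0142
#' @export
assay_sd <- function(conc, assay = assay_error_model(), gamma = 1) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  gamma * (assay$c0 + assay$c1 * conc + assay$c2 * conc^2)
}

#' Population pharmacokinetic model
#'
#' Six [parameter_spec()]s (one per model parameter), log-normal
#' inter-individual variability, and an [assay_error_model()].
#'
#' @param specs list of exactly one `parameter_spec` per parameter name.
#' @param assay an [assay_error_model()].
#' @return object of class `population_model`.
#' @seealso [default_population()] for the packaged final model.
#' @export
population_model <- function(specs, assay = assay_error_model()) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (!setequal(nms, PK_PARAM_NAMES) || anyDuplicated(nms))
    stop("specs must contain exactly one spec per parameter: ",
         paste(PK_PARAM_NAMES, collapse = ", "), call. = FALSE)
  names(specs) <- nms
  structure(list(specs = specs[PK_PARAM_NAMES], assay = assay),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> log-normal IIV\n")
  for (s in x$specs)
    cat(sprintf("  %-5s mean %-7.4g sd %-7.4g %s\n", s$name, s$mean, s$sd,
                s$mode))
  cat(sprintf("  assay SD(C) = %.4f + %.4f C + %.4f C^2\n",
              x$assay$c0, x$assay$c1, x$assay$c2))
  invisible(x)
}

#' The packaged final population model (online-HDF development cohort)
#'
#' CLm 0.473 (SD 0.271) L/h, fr 0.100 fixed, V1 0.278 (0.092) L/kgLBMc,
#' CL12 9.96 L/h fixed, V2 0.686 (0.335) L/kgLBMc, Eec 0.212 (0.069);
#' immunoassay error polynomial as in [assay_error_model()].  The same model
#' ships as a plain-text config at
#' `system.file("extdata", "final_population.csv", package = "vanchd")`.
#'
#' @return a [population_model()].
#' @export
default_population <- function() {
  population_model(list(
    parameter_spec("CLm", 0.473, 0.271, "bayesian"),
    parameter_spec("fr", 0.100, 0, "fixed"),
    parameter_spec("V1", 0.278, 0.092, "bayesian"),
    parameter_spec("CL12", 9.96, 0, "fixed"),
    parameter_spec("V2", 0.686, 0.335, "bayesian"),
    parameter_spec("Eec", 0.212, 0.069, "bayesian")))
}

pop_means <- function(pop) {
  vapply(pop$specs, function(s) s$mean, numeric(1))
}
pop_sds <- function(pop) {
  vapply(pop$specs, function(s) s$sd, numeric(1))
}
pop_modes <- function(pop) {
  vapply(pop$specs, function(s) s$mode, character(1))
}

# log-normal matching natural-scale moments (mean m, sd s):
# sigma^2 = ln(1 + (s/m)^2), mu = ln(m) - sigma^2/2
lnorm_sigma2 <- function(mean, sd) {
  ifelse(mean > 0 & sd > 0, log1p((sd / mean)^2), 0)
}

#' Realize an individual parameter vector from the population model
#'
#' Draws each non-fixed parameter from a log-normal distribution whose
#' natural-scale mean and SD equal the population spec (exact moment
#' matching, not a first-order approximation); fixed parameters are copied.
#' Volumes are scaled from L/kgLBMc to absolute litres with the patient's
#' corrected lean body mass, and residual creatinine clearance is computed
#' from the patient's chemistry.
#'
#' @param pop a [population_model()].
#' @param patient a [patient_record()].
#' @param seed optional integer for reproducible draws.
#' @return [individual_parameters()] (absolute volumes).
#' @export
realize_individual <- function(pop, patient, seed = NULL) {
  stopifnot(inherits(pop, "population_model"),
            inherits(patient, "patient_record"))
  if (!is.null(seed)) set.seed(seed)
  size <- lbmc(patient$weight, patient$height, patient$sex)
  th <- pop_means(pop)
  for (nm in PK_PARAM_NAMES) {
    s <- pop$specs[[nm]]
    if (s$mode != "fixed" && s$sd > 0 && s$mean > 0) {
      s2 <- lnorm_sigma2(s$mean, s$sd)
      th[nm] <- exp(rnorm(1, log(s$mean) - s2 / 2, sqrt(s2)))
    }
  }
  individual_parameters(CLm = th[["CLm"]], fr = th[["fr"]],
                        V1 = th[["V1"]] * size, CL12 = th[["CL12"]],
                        V2 = th[["V2"]] * size, Eec = min(th[["Eec"]], 1),
                        clcr_ml_min = residual_clcr(patient))
}

#' Read/write a population model as a flat config file
#'
#' CSV with columns `name,mean,sd,mode`; the three assay-polynomial
#' coefficients are carried as rows `assay_c0`, `assay_c1`, `assay_c2` with
#' `mode = "assay"`.  `read_population(write_population(pop, f))` restores
#' the model exactly.
#'
#' @param path file path.
#' @param pop a [population_model()].
#' @return `read_population()` returns a [population_model()];
#'   `write_population()` returns `path` invisibly.
#' @export
read_population <- function(path) {
  if (identical(path, "builtin:table2")) return(default_population())
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mean", "sd", "mode")
  if (!all(need %in% names(df)))
    stop("population config must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  arows <- df$mode == "assay"
  av <- setNames(df$mean[arows], df$name[arows])
  assay <- if (any(arows)) {
    assay_error_model(av[["assay_c0"]], av[["assay_c1"]], av[["assay_c2"]])
  } else assay_error_model()
  specs <- lapply(which(!arows), function(i)
    parameter_spec(df$name[i], df$mean[i], df$sd[i], df$mode[i]))
  population_model(specs, assay)
}

#' @rdname read_population
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  rows <- do.call(rbind, lapply(pop$specs, function(s)
    data.frame(name = s$name, mean = s$mean, sd = s$sd, mode = s$mode)))
  arows <- data.frame(name = c("assay_c0", "assay_c1", "assay_c2"),
                      mean = c(pop$assay$c0, pop$assay$c1, pop$assay$c2),
                      sd = 0, mode = "assay")
  write.csv(rbind(rows, arows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
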