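#' Linear variance-scaling models for the most abundant aggregated variant
#'
#' Empirical models linking the fine-structure variance of the most abundant
#' aggregated isotopic peak to its (center) mass,
#' `Var(m_a) = intercept + slope * m_a`. The pinned coefficients are package
#' constants:
#' \describe{
#'   \item{protein}{intercept 1.503e-6 Da^2, slope 3.077e-9 Da (regression
#'     over a large protein database; used here as a fixed constant, not
#'     refit).}
#'   \item{dna}{pure scaling, slope 1.68e-9 Da.}
#'   \item{virus}{pure scaling, slope 2.4e-9 Da (approximately the average
#'     of the protein and DNA slopes, for mixed-composition particles).}
#' }
#'
#' @param class `"protein"`, `"dna"`, `"virus"`, or `"custom"` (requires
#'   `intercept` and `slope`).
#' @param intercept,slope Coefficients for a custom model (Da^2 and Da).
#' @return An object of class `iso_variance_model` with fields `intercept`,
#'   `slope`, `label`.
#' @examples
#' variance_model("protein")
#' @export
variance_model <- function(class = c("protein", "dna", "virus", "custom"),
                           intercept = NULL, slope = NULL) {
  class <- match.arg(class)
  coefs <- switch(class,
    protein = c(1.503e-6, 3.077e-9),
    dna     = c(0, 1.68e-9),
    virus   = c(0, 2.4e-9),
    custom  = {
      if (is.null(intercept) || is.null(slope)) {
        stop("custom model needs `intercept` and `slope`", call. = FALSE)
      }
      c(intercept, slope)
    })
  new_variance_model(coefs[1], coefs[2], class)
}

new_variance_model <- function(intercept, slope, label, fit = NULL) {
  structure(list(intercept = intercept, slope = slope, label = label,
                 fit = fit),
            class = "iso_variance_model")
}

#' @export
print.iso_variance_model <- function(x, ...) {
  cat("<iso_variance_model> ", x$label, ": Var(m_a) = ",
      format(x$intercept), " + ", format(x$slope), " * m_a  [Da^2]\n",
      sep = "")
  invisible(x)
}

#' Predicted fine-structure standard deviation at a given mass
#'
#' `sqrt(intercept + slope * mass)` for a linear variance model.
#'
#' @param model An `iso_variance_model`.
#' @param mass Mass (Da); vectorized.
#' @return Standard deviation(s) in Da.
#' @examples
#' predict_sigma(variance_model("protein"), 34e6)
#' @export
predict_sigma <- function(model, mass) {
  stopifnot(inherits(model, "iso_variance_model"))
  if (any(mass <= 0)) stop("`mass` must be positive", call. = FALSE)
  v <- model$intercept + model$slope * mass
  if (any(v < 0)) stop("model predicts negative variance", call. = FALSE)
  sqrt(v)
}

#' Mass at which adjacent fine-structure clusters start to overlap
#'
#' Solves `intercept + slope * m = sigma_threshold^2` for the mass at which
#' the cluster standard deviation reaches `sigma_threshold`. With the
#' default threshold of 0.5 Da, roughly one third of a Gaussian cluster's
#' probability lies beyond half the ~1 Da spacing to its neighbors, marking
#' the onset of substantial overlap between adjacent aggregated variants.
#'
#' @inheritParams predict_sigma
#' @param sigma_threshold Standard deviation (Da) defining overlap onset.
#' @return Mass in Da.
#' @examples
#' overlap_onset_mass(variance_model("protein"))  # ~81.25 MDa
#' @export
overlap_onset_mass <- function(model, sigma_threshold = 0.5) {
  stopifnot(inherits(model, "iso_variance_model"))
  if (sigma_threshold <= 0) {
    stop("`sigma_threshold` must be positive", call. = FALSE)
  }
  if (model$slope <= 0) stop("model slope must be positive", call. = FALSE)
  if (sigma_threshold^2 <= model$intercept) {
    stop("threshold variance does not exceed the model intercept; ",
         "no onset mass exists", call. = FALSE)
  }
  (sigma_threshold^2 - model$intercept) / model$slope
}

#' Fit a linear variance model to computed variances
#'
#' Ordinary least squares of fine-structure variance against mass, e.g. for
#' checking that directly computed poly-averagine variances are consistent
#' with the pinned protein coefficients.
#'
#' @param data A data frame with columns `mass` (Da) and `variance` (Da^2).
#' @param label Label for the fitted model.
#' @return An `iso_variance_model` carrying the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(mass = c(1e5, 2e5, 4e5),
#'                     variance = 1.5e-6 + 3e-9 * mass)
#' fit_variance_model(d)
#' @export
fit_variance_model <- function(data, label = "custom") {
  if (!all(c("mass", "variance") %in% names(data))) {
    stop("`data` needs columns `mass` and `variance`", call. = FALSE)
  }
  if (length(unique(data$mass)) < 2) {
    stop("need at least 2 distinct masses to fit", call. = FALSE)
  }
  fit <- stats::lm(variance ~ mass, data = data)
  cf <- stats::coef(fit)
  new_variance_model(unname(cf[1]), unname(cf[2]), label, fit = fit)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance model
#'
#' @param x An `iso_variance_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`, and,
#'   for fitted models, `std.error`).
#' @export
tidy.iso_variance_model <- function(x, ...) {
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
  if (!is.null(x$fit)) {
    out$std.error <- unname(sqrt(diag(stats::vcov(x$fit))))
  }
  out
}

#' Glance at a variance model
#'
#' @inheritParams tidy.iso_variance_model
#' @return A one-row tibble with `label`, `intercept`, `slope`,
#'   `overlap_onset_mass` (at the 0.5 Da threshold; `NA` if none exists)
#'   and, for fitted models, `r.squared` and `nobs`.
#' @export
glance.iso_variance_model <- function(x, ...) {
  onset <- tryCatch(overlap_onset_mass(x), error = function(e) NA_real_)
  out <- tibble::tibble(label = x$label, intercept = x$intercept,
                        slope = x$slope, overlap_onset_mass = onset)
  if (!is.null(x$fit)) {
    out$r.squared <- summary(x$fit)$r.squared
    out$nobs <- stats::nobs(x$fit)
  }
  out
}

#' Thermophysical configuration for the thermorelativistic mass uncertainty
#'
#' @param temperature Ion internal temperature in K.
#' @param dof_per_atom Heat-capacity factor: the ion's heat capacity is
#'   `C = dof_per_atom * N_atoms * k_B`. The default 3/2 is the equipartition
#'   value for three quadratic degrees of freedom per atom.
#' @param k_B Boltzmann constant (J/K), CODATA exact value.
#' @param c Speed of light (m/s), exact.
#' @param u Atomic mass unit (kg/Da), CODATA.
#' @return A list of class `iso_thermo_config`.
#' @export
thermo_config <- function(temperature = 300, dof_per_atom = 3 / 2,
                          k_B = 1.380649e-23, c = 299792458,
                          u = 1.66053906660e-27) {
  if (temperature < 0) stop("`temperature` must be >= 0", call. = FALSE)
  if (dof_per_atom <= 0) stop("`dof_per_atom` must be > 0", call. = FALSE)
  structure(list(temperature = temperature, dof_per_atom = dof_per_atom,
                 k_B = k_B, c = c, u = u),
            class = "iso_thermo_config")
}

#' Thermorelativistic mass uncertainty of an isolated ion
#'
#' An isolated ion at internal temperature T carries a fluctuating internal
#' energy with standard deviation `sigma_E = sqrt(k_B * T^2 * C)`
#' (canonical-ensemble fluctuation), where `C = dof_per_atom * N_atoms * k_B`
#' is its heat capacity. Through E = m c^2 the energy fluctuation is an
#' irreducible mass uncertainty `dm = sigma_E / c^2` that no instrument can
#' resolve below; it grows as the square root of the number of atoms (hence
#' of the molecular weight at fixed composition) and linearly in T.
#'
#' @inheritParams monoisotopic_mass
#' @param config An [thermo_config()] object.
#' @return A one-row tibble with `n_atoms`, `temperature`, `sigma_E_J`,
#'   `dm_kg` and `dm_Da`.
#' @examples
#' thermorelativistic_dm(averagine_formula(2000))
#' @export
thermorelativistic_dm <- function(formula, config = thermo_config(),
                                  table = isotope_table()) {
  stopifnot(inherits(config, "iso_thermo_config"))
  f <- as_iso_formula(formula, table)
  n_atoms <- sum(f)
  heat_cap <- config$dof_per_atom * n_atoms * config$k_B
  sigma_E <- sqrt(config$k_B * config$temperature^2 * heat_cap)
  dm_kg <- sigma_E / config$c^2
  tibble::tibble(n_atoms = n_atoms, temperature = config$temperature,
                 sigma_E_J = sigma_E, dm_kg = dm_kg,
                 dm_Da = dm_kg / config$u)
}

#' Resolvability report for the most abundant aggregated variant
#'
#' Bundles, for the most abundant aggregated variant of a molecule, the
#' quantities that decide whether its fine structure is resolvable: the
#' cluster standard deviation, the closed-form maximum spread, the exact
#' fine-peak count, the mean peak spacing under both width conventions, the
#' thermorelativistic mass uncertainty, and the spacing-to-uncertainty
#' ratios. A ratio well below 1 means the fine peaks are packed far more
#' densely than the thermorelativistic width and cannot be resolved even at
#' infinite instrumental resolution.
#'
#' @inheritParams thermorelativistic_dm
#' @param k Width multiplier for the sigma-based spacing (total width
#'   `k * sigma`).
#' @return A one-row tibble with `formula`, `j` (most abundant variant),
#'   `q_j`, `center_mass`, `sigma`, `spread`, `n_fine_peaks`,
#'   `spacing_spread`, `spacing_sigma`, `dm_Da`, `spacing_spread_over_dm`,
#'   `spacing_sigma_over_dm`.
#' @examples
#' resolvability_report("C2H2N2O2S2")
#' @export
resolvability_report <- function(formula, table = isotope_table(),
                                 config = thermo_config(), k = 4) {
  f <- as_iso_formula(formula, table)
  agg <- aggregated_distribution(f, table)
  jstar <- most_abundant_variant(agg)
  row <- which(agg$j == jstar)
  n <- count_fine_peaks(f, jstar, table)
  spread <- max_spread(f, jstar, table, mode = "eq7")
  sp_spread <- if (n >= 2) spread / n else NA_real_
  sp_sigma <- if (n >= 2) k * agg$sigma[row] / n else NA_real_
  dm <- thermorelativistic_dm(f, config, table)$dm_Da
  tibble::tibble(
    formula = format(f),
    j = jstar,
    q_j = agg$q[row],
    center_mass = agg$center_mass[row],
    sigma = agg$sigma[row],
    spread = spread,
    n_fine_peaks = n,
    spacing_spread = sp_spread,
    spacing_sigma = sp_sigma,
    dm_Da = dm,
    spacing_spread_over_dm = sp_spread / dm,
    spacing_sigma_over_dm = sp_sigma / dm
  )
}
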