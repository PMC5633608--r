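#' Physical constants used by the growth models
#'
#' The Boltzmann constant in electron volts per kelvin and the offset used to
#' convert degrees Celsius to kelvin. Both are fixed at construction; the
#' Arrhenius growth models take absolute temperature in kelvin.
#'
#' @return A named list with elements `boltzmann_k` (eV K^-1) and
#'   `celsius_to_kelvin_offset` (K).
#' @examples
#' physical_constants()$boltzmann_k
#' @export
physical_constants <- function() {
  list(boltzmann_k = 8.62e-5, celsius_to_kelvin_offset = 273.15)
}

#' Temperature-growth coefficients for the picophytoplankton groups
#'
#' Constructs the default coefficient set: concave-down binomial polynomials
#' mu = a0 + a1*T + a2*T^2 (T in degrees Celsius) for the two high-light
#' adapted Prochlorococcus ecotypes, and Arrhenius forms
#' ln(mu) = -E/(k*T_K) + b for Synechococcus and for the picoeukaryote
#' community. Activation energies E are in eV; intercepts are natural logs of
#' the normalisation constant. The Synechococcus relationship was fitted over
#' 10-34 degrees C; evaluation outside that range is permitted but flagged.
#' The picoeukaryote relationship holds for total chlorophyll above
#' 0.5 mg m^-3; below that threshold a warning flag is raised and an optional
#' bias divisor of 1.58 can be applied (off by default), reflecting an average
#' 58 percent overestimate of picoeukaryote growth in low-chlorophyll water.
#'
#' @return An object of class `growth_params`: a nested list with components
#'   `prochlorococcus` (per-ecotype polynomial coefficients `a0`, `a1`, `a2`),
#'   `synechococcus` and `picoeukaryotes` (each with `activation_energy_ev`,
#'   `intercept_ln_mu_c`, confidence bounds and, for Synechococcus, the fitted
#'   temperature range), plus `constants` and a format `version`.
#' @seealso [read_growth_params()] to load a user-supplied coefficient file.
#' @examples
#' gp <- growth_params()
#' gp$synechococcus$activation_energy_ev
#' @export
growth_params <- function() {
  gp <- list(
    version = 1L,
    prochlorococcus = list(
      eMIT9312 = list(a0 = -4.17, a1 = 0.40, a2 = -0.0086),
      eMED4    = list(a0 = -1.11, a1 = 0.14, a2 = -0.0035)
    ),
    synechococcus = list(
      activation_energy_ev = 0.73,
      ci_activation_energy = c(0.60, 0.88),
      intercept_ln_mu_c = 28.13,
      ci_intercept = c(23.20, 34.15),
      fit_range_c = c(10, 34)
    ),
    picoeukaryotes = list(
      activation_energy_ev = 0.86,
      ci_activation_energy = c(0.68, 1.07),
      intercept_ln_mu_c = 33.85,
      ci_intercept = c(26.94, 42.35),
      chl_threshold_mg_m3 = 0.5,
      low_chl_bias_divisor = 1.58
    ),
    constants = physical_constants()
  )
  class(gp) <- "growth_params"
  validate_growth_params(gp)
}

validate_growth_params <- function(gp) {
  stopifnot(is.list(gp), !is.null(gp$prochlorococcus), !is.null(gp$synechococcus),
            !is.null(gp$picoeukaryotes))
  for (eco in c("eMIT9312", "eMED4")) {
    co <- gp$prochlorococcus[[eco]]
    if (is.null(co) || !all(c("a0", "a1", "a2") %in% names(co)))
      stop("polynomial coefficients a0, a1, a2 required for ecotype ", eco)
    if (co$a2 >= 0)
      stop("ecotype ", eco, ": a2 must be negative (single interior maximum)")
  }
  for (grp in c("synechococcus", "picoeukaryotes")) {
    ar <- gp[[grp]]
    if (ar$activation_energy_ev <= 0)
      stop(grp, ": activation energy must be positive")
    ci <- ar$ci_activation_energy
    if (!is.null(ci) && !(ci[1] <= ar$activation_energy_ev &&
                          ar$activation_energy_ev <= ci[2]))
      stop(grp, ": CI must bracket the activation energy point estimate")
  }
  if (is.null(gp$constants)) gp$constants <- physical_constants()
  if (gp$constants$boltzmann_k <= 0) stop("Boltzmann constant must be positive")
  gp
}

#' Read growth coefficients from a YAML key-value file
#'
#' Loads a coefficient file with the same structure that [growth_params()]
#' builds in code (the shipped copy is at
#' `system.file("extdata", "growth_coefficients.yml", package = "picoPP")`),
#' validates it, and returns a `growth_params` object. Users can override any
#' coefficient by editing a copy of the shipped file.
#'
#' @param path Path to a YAML file.
#' @return A validated `growth_params` object.
#' @export
read_growth_params <- function(path) {
  if (!file.exists(path)) stop("growth coefficient file not found: ", path)
  gp <- yaml::read_yaml(path)
  gp$constants <- physical_constants()
  for (grp in c("synechococcus", "picoeukaryotes")) {
    for (fld in c("ci_activation_energy", "ci_intercept", "fit_range_c"))
      if (!is.null(gp[[grp]][[fld]])) gp[[grp]][[fld]] <- as.numeric(gp[[grp]][[fld]])
  }
  class(gp) <- "growth_params"
  validate_growth_params(gp)
}

growth_result <- function(mu, clamped = FALSE, low_chl_warning = FALSE,
                          extrapolated = FALSE) {
  n <- length(mu)
  out <- data.frame(
    mu = mu,
    clamped = rep_len(clamped, n),
    low_chl_warning = rep_len(low_chl_warning, n),
    extrapolated = rep_len(extrapolated, n)
  )
  class(out) <- c("growth_result", "data.frame")
  out
}

check_temperature <- function(temperature, absolute_floor = FALSE) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)))
    stop("temperature must be finite and numeric")
  if (absolute_floor && any(temperature <= -273.15))
    stop("temperature must exceed absolute zero (-273.15 degrees C)")
  invisible(temperature)
}

arrhenius_mu <- function(temperature_c, activation_energy_ev, intercept,
                         constants = physical_constants()) {
  tk <- temperature_c + constants$celsius_to_kelvin_offset
  exp(-activation_energy_ev / (constants$boltzmann_k * tk) + intercept)
}

#' Prochlorococcus growth rate from temperature
#'
#' Evaluates the binomial polynomial mu = a0 + a1*T + a2*T^2 for a high-light
#' adapted Prochlorococcus ecotype, or the arithmetic mean of the two shipped
#' ecotypes (`"mean"`, the default, since no mixing rule is available for
#' field populations where both co-occur). Negative polynomial values, which
#' arise at cold temperatures outside the ecotypes' thermal niche, are clamped
#' to zero and flagged rather than returned.
#'
#' @param temperature Sea temperature, degrees Celsius (vectorised).
#' @param ecotype One of `"mean"`, `"eMIT9312"`, `"eMED4"`.
#' @param params A `growth_params` object.
#' @return A `growth_result` data frame with columns `mu` (d^-1, >= 0),
#'   `clamped`, `low_chl_warning` (always `FALSE` here) and `extrapolated`.
#' @examples
#' growth_prochlorococcus(25, "eMIT9312")$mu
#' growth_prochlorococcus(5, "eMIT9312")$clamped  # below thermal niche
#' @export
growth_prochlorococcus <- function(temperature,
                                   ecotype = c("mean", "eMIT9312", "eMED4"),
                                   params = growth_params()) {
  check_temperature(temperature)
  ecotype <- match.arg(ecotype)
  poly_mu <- function(co) co$a0 + co$a1 * temperature + co$a2 * temperature^2
  raw <- if (ecotype == "mean") {
    (poly_mu(params$prochlorococcus$eMIT9312) +
       poly_mu(params$prochlorococcus$eMED4)) / 2
  } else {
    poly_mu(params$prochlorococcus[[ecotype]])
  }
  growth_result(pmax(raw, 0), clamped = raw < 0)
}

#' Synechococcus growth rate from temperature
#'
#' Arrhenius model ln(mu) = -E/(k*T_K) + b with E = 0.73 eV fitted over
#' 10-34 degrees C; strictly increasing in temperature and always positive.
#' Temperatures outside the fitted range are still evaluated but the result
#' carries `extrapolated = TRUE` (cold winter shelf seas sit below 10 degrees C
#' and the advisory flag keeps that visible).
#'
#' @inheritParams growth_prochlorococcus
#' @return A `growth_result` data frame; `clamped` is always `FALSE`.
#' @examples
#' growth_synechococcus(c(10, 20, 30))$mu
#' @export
growth_synechococcus <- function(temperature, params = growth_params()) {
  check_temperature(temperature, absolute_floor = TRUE)
  sy <- params$synechococcus
  mu <- arrhenius_mu(temperature, sy$activation_energy_ev, sy$intercept_ln_mu_c,
                     params$constants)
  rng <- sy$fit_range_c
  extra <- if (is.null(rng)) FALSE else temperature < rng[1] | temperature > rng[2]
  growth_result(mu, extrapolated = extra)
}

#' Picoeukaryote community growth rate from temperature
#'
#' Arrhenius model ln(mu) = -E/(k*T_K) + b with E = 0.86 eV, fitted to
#' field-measured community growth where total chlorophyll exceeds
#' 0.5 mg m^-3. Below that threshold the temperature relationship is not
#' significant and the model tends to overestimate growth by an average of
#' 58 percent; the rate is still computed but flagged with
#' `low_chl_warning = TRUE`, and `bias_correct = TRUE` divides flagged rates
#' by 1.58 as a crude correction.
#'
#' @inheritParams growth_prochlorococcus
#' @param chlorophyll Total chlorophyll, mg m^-3 (vectorised, recycled).
#' @param bias_correct Apply the 1.58 divisor to low-chlorophyll rates?
#' @return A `growth_result` data frame.
#' @examples
#' growth_picoeukaryotes(20, chlorophyll = 1.2)$mu
#' growth_picoeukaryotes(20, chlorophyll = 0.1)$low_chl_warning
#' @export
growth_picoeukaryotes <- function(temperature, chlorophyll,
                                  params = growth_params(),
                                  bias_correct = FALSE) {
  check_temperature(temperature, absolute_floor = TRUE)
  if (!is.numeric(chlorophyll) || any(is.na(chlorophyll)) || any(chlorophyll < 0))
    stop("chlorophyll must be non-negative")
  eu <- params$picoeukaryotes
  mu <- arrhenius_mu(temperature, eu$activation_energy_ev, eu$intercept_ln_mu_c,
                     params$constants)
  n <- max(length(temperature), length(chlorophyll))
  mu <- rep_len(mu, n)
  low <- rep_len(chlorophyll, n) < eu$chl_threshold_mg_m3
  if (bias_correct) mu[low] <- mu[low] / eu$low_chl_bias_divisor
  growth_result(mu, low_chl_warning = low)
}
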