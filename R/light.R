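#' Euphotic-zone depth from the diffuse attenuation coefficient
#'
#' Depth at which downwelling light falls to 1 percent of its surface value,
#' Z_eu = -ln(0.01)/k490 = 4.60517.../k490 metres. Strictly positive and
#' strictly decreasing in k490. (The defining relation is exp(-k490 * Z_eu)
#' = 0.01; the sign is fixed so depth is a positive number of metres.)
#'
#' @param k490 Diffuse attenuation coefficient at 490 nm, m^-1 (> 0,
#'   vectorised).
#' @return Euphotic depth in metres.
#' @examples
#' euphotic_depth(0.0460517)  # ~100 m, clear ocean
#' @export
euphotic_depth <- function(k490) {
  if (!is.numeric(k490) || any(is.na(k490)) || any(k490 <= 0))
    stop("k490 must be positive")
  -log(0.01) / k490
}

#' Surface-irradiance term of the depth-integrated production model
#'
#' Saturating function h(I0) = 0.66125 * I0 / (I0 + 4.1) describing how
#' surface photosynthetically active radiation shapes the depth-dependent
#' profile of carbon fixation. Dimensionless, monotone increasing, bounded in
#' [0, 0.66125); half its asymptote at I0 = 4.1 mol photons m^-2 d^-1.
#'
#' @param I0 Surface PAR, mol photons m^-2 d^-1 (>= 0, vectorised).
#' @return Dimensionless factor in [0, 0.66125).
#' @examples
#' light_limitation(c(0, 4.1, 40.4))
#' @export
light_limitation <- function(I0) {
  if (!is.numeric(I0) || any(is.na(I0)) || any(I0 < 0))
    stop("I0 must be non-negative")
  0.66125 * I0 / (I0 + 4.1)
}

#' Volumetric primary production
#'
#' PP = C x mu: surface-layer carbon biomass times specific growth rate,
#' in mg C m^-3 d^-1. Exactly linear in each argument.
#'
#' @param biomass Carbon biomass, mg C m^-3 (>= 0).
#' @param mu Growth rate, d^-1 (>= 0).
#' @return Volumetric production, mg C m^-3 d^-1.
#' @export
volumetric_pp <- function(biomass, mu) {
  if (any(biomass < 0, na.rm = TRUE) || any(mu < 0, na.rm = TRUE))
    stop("biomass and mu must be non-negative")
  biomass * mu
}

#' Depth-integrated primary production
#'
#' PP = C x mu x Z_eu x h(I0): the volumetric rate scaled over the euphotic
#' column by its depth and the surface-irradiance factor, in mg C m^-2 d^-1.
#'
#' @param biomass Carbon biomass, mg C m^-3 (>= 0).
#' @param mu Growth rate, d^-1 (>= 0).
#' @param zeu Euphotic depth, m (>= 0).
#' @param h Dimensionless surface-irradiance factor (>= 0).
#' @return Depth-integrated production, mg C m^-2 d^-1.
#' @export
integrated_pp <- function(biomass, mu, zeu, h) {
  if (any(c(biomass, mu, zeu, h) < 0, na.rm = TRUE))
    stop("all arguments must be non-negative")
  biomass * mu * zeu * h
}

# resolve the euphotic depth for each record according to the source policy
resolve_zeu <- function(records, zeu_source = c("auto", "external", "formula")) {
  zeu_source <- match.arg(zeu_source)
  n <- nrow(records)
  ext <- if ("zeu_m" %in% names(records)) as.numeric(records$zeu_m) else rep(NA_real_, n)
  k <- if ("k490_m1" %in% names(records)) as.numeric(records$k490_m1) else rep(NA_real_, n)
  form <- ifelse(is.na(k) | k <= 0, NA_real_, -log(0.01) / pmax(k, .Machine$double.eps))
  zeu <- switch(zeu_source,
    external = ext,
    formula = form,
    auto = ifelse(!is.na(ext), ext, form))
  src <- switch(zeu_source,
    external = rep("external_iop", n),
    formula = rep("k490_formula", n),
    auto = ifelse(!is.na(ext), "external_iop", "k490_formula"))
  if (any(is.na(zeu)))
    stop("no euphotic depth available for record(s) ",
         paste(utils::head(which(is.na(zeu)), 5), collapse = ", "),
         " under zeu_source = '", zeu_source,
         "': supply zeu_m and/or k490_m1")
  list(zeu = zeu, source = src)
}

#' Production estimate for a single station record
#'
#' Orchestrates the full pathway for one record: temperature-dependent growth
#' rates per group, abundance-to-carbon conversion, euphotic depth (external
#' inherent-optical-properties product when present, otherwise the k490
#' formula), the surface-irradiance term, and the volumetric and
#' depth-integrated products. This is the single-record convenience around
#' [cbpm()], which does the same for a whole station table.
#'
#' @param record One-row data frame or named list following the station
#'   schema (see [read_stations()]); must carry `sst_c` and either `k490_m1`
#'   or `zeu_m`.
#' @param ccf A `ccf_table`.
#' @param params A `growth_params` object.
#' @param ecotype Prochlorococcus ecotype mode (`"mean"`, `"eMIT9312"`,
#'   `"eMED4"`).
#' @param zeu_source `"auto"` (external wins when present), `"external"`,
#'   or `"formula"`.
#' @param which_ccf CCF column: `"average"`, `"min"`, `"max"`.
#' @param bias_correct Apply the low-chlorophyll picoeukaryote divisor?
#' @return A `production_estimate`: list with named vectors `volumetric`
#'   (mg C m^-3 d^-1) and `integrated` (mg C m^-2 d^-1) over
#'   prochlorococcus / synechococcus / picoeukaryotes / total, the growth
#'   rates `mu`, `zeu`, `h`, `zeu_source`, and logical `flags` (`clamped`,
#'   `low_chl_warning`, `extrapolated`) plus `missing_groups`.
#' @examples
#' rec <- list(sst_c = 21.1, chl_mgm3 = 4.7, par_mol_m2_d = 49.3,
#'             zeu_m = 15.1, syn_cells_ml = 2.2e4, euk_cells_ml = 4.8e3)
#' estimate_station(rec)
#' @export
estimate_station <- function(record, ccf = ccf_table("direct"),
                             params = growth_params(), ecotype = "mean",
                             zeu_source = "auto", which_ccf = "average",
                             bias_correct = FALSE) {
  rec <- as.data.frame(record[!vapply(record, is.null, logical(1))],
                       stringsAsFactors = FALSE)
  fit <- cbpm(rec, ccf = ccf, params = params, ecotype = ecotype,
              zeu_source = zeu_source, which_ccf = which_ccf,
              bias_correct = bias_correct)
  e <- fit$estimates
  pick <- function(prefix) {
    v <- unlist(e[1, paste0(prefix, c("pro", "syn", "euk", "total"))])
    names(v) <- c(PICO_GROUPS, "total")
    v
  }
  out <- list(volumetric = pick("pp_vol_"), integrated = pick("pp_int_"),
              mu = stats::setNames(unlist(e[1, paste0("mu_", c("pro", "syn", "euk"))]),
                                   PICO_GROUPS),
              zeu = e$zeu_m_used[1], h = e$h_i0[1], zeu_source = e$zeu_source[1],
              flags = c(clamped = e$flag_clamped[1],
                        low_chl_warning = e$flag_low_chl[1],
                        extrapolated = e$flag_extrapolated[1]),
              missing_groups = PICO_GROUPS[c(e$flag_pro_missing[1],
                                             e$flag_syn_missing[1],
                                             e$flag_euk_missing[1])])
  class(out) <- "production_estimate"
  out
}

#' @export
print.production_estimate <- function(x, digits = 4, ...) {
  cat("Picophytoplankton production estimate (Z_eu source: ", x$zeu_source,
      ")\n", sep = "")
  m <- rbind(`mu (d^-1)` = c(x$mu, NA),
             `volumetric PP (mg C m^-3 d^-1)` = x$volumetric,
             `integrated PP (mg C m^-2 d^-1)` = x$integrated)
  colnames(m) <- c("Pro", "Syn", "Euk", "total")
  print(round(m, digits))
  fl <- names(x$flags)[x$flags]
  if (length(fl)) cat("flags:", paste(fl, collapse = ", "), "\n")
  if (length(x$missing_groups))
    cat("groups absent (treated as zero):",
        paste(x$missing_groups, collapse = ", "), "\n")
  invisible(x)
}
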