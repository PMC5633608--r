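#' Reduced major axis (Model II) regression
#'
#' Fits the reduced major axis line, the Model II regression appropriate when
#' both variables carry error (as when comparing a model estimate with a
#' measured rate): slope = sign(r) * s_y / s_x and intercept =
#' mean(y) - slope * mean(x), with r^2 the squared Pearson correlation on the
#' fitted scale. Confidence intervals come from a seeded bias-corrected
#' percentile bootstrap over paired resamples (default, 1999 resamples) or
#' from the closed-form interval
#' slope * (sqrt(B + 1) +/- sqrt(B)), B = t^2 (1 - r^2)/(n - 2).
#'
#' @param x Measured values (x axis), or a formula `y ~ x`.
#' @param y Estimated values (y axis), paired with `x`.
#' @param transform `"identity"` or `"log10"`. Under `"log10"`, pairs with a
#'   non-positive member are dropped with a message and counted in
#'   `n_dropped`; the fit, r^2 and intervals are on the log10 scale.
#' @param ci_method `"bootstrap"` or `"analytic"`.
#' @param nboot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap (the global RNG state is left
#'   untouched); `NULL` uses the current RNG stream.
#' @param conf Confidence level.
#' @param ... Passed between methods.
#' @return An object of class `rma_fit` with components `slope`, `intercept`,
#'   `r_squared`, `n`, `slope_ci`, `intercept_ci`, `transform`, `ci_method`,
#'   `p_value` (from the correlation t statistic), `n_dropped`, and the
#'   (transformed) data `x`, `y`.
#' @examples
#' set.seed(1)
#' x <- rlnorm(50); y <- 1.7 * x * rlnorm(50, sd = 0.1)
#' fit <- rma_fit(x, y, seed = 7, nboot = 199)
#' coef(fit)
#' confint(fit)
#' @export
rma_fit <- function(x, ...) UseMethod("rma_fit")

#' @rdname rma_fit
#' @export
rma_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2) stop("formula must be of the form y ~ x")
  rma_fit.default(mf[[2]], mf[[1]], ...)
}

#' @rdname rma_fit
#' @export
rma_fit.default <- function(x, y, transform = c("identity", "log10"),
                            ci_method = c("bootstrap", "analytic"),
                            nboot = 1999, seed = NULL, conf = 0.95, ...) {
  transform <- match.arg(transform)
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (transform == "log10") {
    pos <- x > 0 & y > 0
    if (any(!pos))
      message("dropping ", sum(!pos), " pair(s) with non-positive values ",
              "for the log10 fit")
    n_dropped <- n_dropped + sum(!pos)
    x <- log10(x[pos]); y <- log10(y[pos])
  }
  n <- length(x)
  if (n < 3) stop("at least 3 paired finite observations are required")
  est <- rma_point(x, y)

  alpha <- (1 - conf) / 2
  if (ci_method == "analytic") {
    tcrit <- stats::qt(1 - alpha, df = n - 2)
    B <- tcrit^2 * (1 - est["r2"]) / (n - 2)
    slope_ci <- est["slope"] * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
    slope_ci <- sort(slope_ci)
    icpts <- mean(y) - slope_ci * mean(x)
    intercept_ci <- sort(icpts)
  } else {
    bs <- with_seed(seed, {
      replicate(nboot, {
        idx <- sample.int(n, n, replace = TRUE)
        rma_point(x[idx], y[idx])[c("slope", "intercept")]
      })
    })
    slope_ci <- bc_percentile(bs["slope", ], est["slope"], alpha)
    intercept_ci <- bc_percentile(bs["intercept", ], est["intercept"], alpha)
  }

  r <- sqrt(est["r2"]) * sign(est["slope"])
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  out <- list(slope = unname(est["slope"]), intercept = unname(est["intercept"]),
              r_squared = unname(est["r2"]), n = n,
              slope_ci = unname(slope_ci), intercept_ci = unname(intercept_ci),
              transform = transform, ci_method = ci_method, conf = conf,
              nboot = if (ci_method == "bootstrap") nboot else NA_integer_,
              seed = seed, p_value = unname(p), n_dropped = n_dropped,
              x = x, y = y, call = match.call())
  class(out) <- "rma_fit"
  out
}

# point estimate computed from raw moments (no calls to sd/cor, so the test
# suite can cross-check against the stats-package composition independently)
rma_point <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  if (sxx <= 0 || syy <= 0)
    stop("degenerate fit: zero variance in x or y")
  r <- sxy / sqrt(sxx * syy)
  slope <- sign(r) * sqrt(syy / sxx)
  if (r == 0) slope <- sqrt(syy / sxx)  # sign undefined at exactly r = 0
  c(slope = slope, intercept = my - slope * mx, r2 = r^2)
}

# bias-corrected percentile interval
bc_percentile <- function(draws, point, alpha) {
  draws <- draws[is.finite(draws)]
  z0 <- stats::qnorm(mean(draws < point) + 0.5 * mean(draws == point))
  if (!is.finite(z0)) z0 <- 0
  lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  unname(stats::quantile(draws, c(lo, hi), type = 7))
}

# evaluate `expr` under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.rma_fit <- function(x, digits = 4, ...) {
  cat("Reduced major axis (Model II) regression",
      if (x$transform == "log10") "on log10 scale", "\n")
  cat(sprintf("  slope     %.*g  (%.0f%% CI %.*g to %.*g)\n", digits, x$slope,
              100 * x$conf, digits, x$slope_ci[1], digits, x$slope_ci[2]))
  cat(sprintf("  intercept %.*g  (%.0f%% CI %.*g to %.*g)\n", digits,
              x$intercept, 100 * x$conf, digits, x$intercept_ci[1], digits,
              x$intercept_ci[2]))
  cat(sprintf("  r^2 = %.*g, n = %d, p = %.3g (%s CI%s)\n", digits,
              x$r_squared, x$n, x$p_value, x$ci_method,
              if (x$ci_method == "bootstrap")
                sprintf(", %d resamples", x$nboot) else ""))
  if (x$n_dropped > 0) cat("  dropped pairs:", x$n_dropped, "\n")
  invisible(x)
}

#' @export
summary.rma_fit <- function(object, ...) object

#' @export
coef.rma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.rma_fit <- function(object, parm = c("slope", "intercept"), ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  m <- rbind(slope = object$slope_ci, intercept = object$intercept_ci)
  colnames(m) <- paste0(100 * c((1 - object$conf) / 2,
                                1 - (1 - object$conf) / 2), "%")
  m[parm, , drop = FALSE]
}

#' @export
predict.rma_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else newdata
  if (object$transform == "log10" && !is.null(newdata)) xx <- log10(xx)
  object$intercept + object$slope * xx
}

#' @export
residuals.rma_fit <- function(object, ...) {
  object$y - (object$intercept + object$slope * object$x)
}

#' @export
plot.rma_fit <- function(x, ...) {
  lab <- if (x$transform == "log10") "log10 PP" else "PP"
  graphics::plot(x$x, x$y, xlab = paste("measured", lab),
                 ylab = paste("estimated", lab), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.7), ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "firebrick", lwd = 2)
  graphics::abline(a = 0, b = 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("RMA: y = %.2f + %.2f x, r^2 = %.2f",
                                      x$intercept, x$slope, x$r_squared),
                              "1:1"),
                   col = c("firebrick", "black"), lty = c(1, 2), lwd = c(2, 1))
  invisible(x)
}

#' Validate model production against measured 14C uptake
#'
#' Computes volumetric production (the C x mu pathway, the scale on which
#' measured rates are reported) for every record carrying a measured value
#' `pp14c`, then fits reduced major axis regressions of estimated on measured
#' production on the raw and the log10 scale, and reports the mean +/- sd of
#' estimated biomass and production under both shipped CCF sets. The raw-scale
#' slope minus one, times 100, is reported as the average overestimation
#' percentage of the model relative to the measurements.
#'
#' @param data Station data frame including a `pp14c` column
#'   (mg C m^-3 d^-1).
#' @param ccf_set `"direct"` or `"in_situ"` — the set used for the regression
#'   pathway (means are reported for both).
#' @param params,ecotype,bias_correct Passed to the growth models.
#' @param ci_method,nboot,seed,conf Passed to [rma_fit()].
#' @return A `cbpm_validation` object: list with `rma_raw`, `rma_log10`,
#'   `means` (per-CCF-set mean +/- sd of biomass and volumetric PP),
#'   `overestimation_percent`, `n`, `n_dropped_log10`, and the scatter data.
#' @examples
#' cfg <- synthetic_config(n_stations = 60, seed = 3, bias = 1.5)
#' st <- generate_stations(cfg)
#' rep <- compare_to_measured(st, nboot = 199, seed = 3)
#' rep
#' @export
compare_to_measured <- function(data, ccf_set = c("direct", "in_situ"),
                                params = growth_params(), ecotype = "mean",
                                bias_correct = FALSE,
                                ci_method = "bootstrap", nboot = 1999,
                                seed = NULL, conf = 0.95) {
  ccf_set <- match.arg(ccf_set)
  if (!"pp14c" %in% names(data)) stop("data must carry measured PP (pp14c)")
  data <- as.data.frame(data)
  data <- data[is.finite(data$pp14c), , drop = FALSE]
  if (nrow(data) < 3)
    stop("at least 3 records with measured PP and model inputs are required")

  means <- lapply(c(direct = "direct", in_situ = "in_situ"), function(s) {
    fit <- cbpm(data, ccf = ccf_table(s), params = params, ecotype = ecotype,
                bias_correct = bias_correct, integrate = FALSE)
    e <- fit$estimates
    bio <- rowSums(sweep(abundance_matrix_zero(data), 2,
                         ccf_table(s)[PICO_GROUPS, "average"] * 1e-6, `*`))
    c(biomass_mean = mean(bio), biomass_sd = stats::sd(bio),
      pp_mean = mean(e$pp_vol_total), pp_sd = stats::sd(e$pp_vol_total))
  })

  fit <- cbpm(data, ccf = ccf_table(ccf_set), params = params,
              ecotype = ecotype, bias_correct = bias_correct, integrate = FALSE)
  est <- fit$estimates$pp_vol_total
  meas <- data$pp14c
  rma_raw <- rma_fit(meas, est, transform = "identity", ci_method = ci_method,
                     nboot = nboot, seed = seed, conf = conf)
  rma_log <- rma_fit(meas, est, transform = "log10", ci_method = ci_method,
                     nboot = nboot, seed = seed, conf = conf)

  out <- list(rma_raw = rma_raw, rma_log10 = rma_log,
              means = do.call(rbind, means),
              overestimation_percent = (rma_raw$slope - 1) * 100,
              n = rma_raw$n, n_dropped_log10 = rma_log$n_dropped,
              ccf_set = ccf_set,
              scatter = data.frame(measured = meas, estimated = est,
                                   flag_clamped = fit$estimates$flag_clamped,
                                   flag_low_chl = fit$estimates$flag_low_chl,
                                   flag_extrapolated = fit$estimates$flag_extrapolated))
  class(out) <- "cbpm_validation"
  out
}

abundance_matrix_zero <- function(records) {
  m <- abundance_matrix(records)
  m[is.na(m)] <- 0
  m
}

#' @export
print.cbpm_validation <- function(x, digits = 3, ...) {
  cat("Validation of carbon-based production against measured 14C uptake\n")
  cat("  n =", x$n, " (regression CCF set:", x$ccf_set, ")\n")
  cat(sprintf("  raw scale:   slope %.3g (CI %.3g-%.3g), intercept %.3g, r^2 %.3g\n",
              x$rma_raw$slope, x$rma_raw$slope_ci[1], x$rma_raw$slope_ci[2],
              x$rma_raw$intercept, x$rma_raw$r_squared))
  cat(sprintf("  log10 scale: slope %.3g (CI %.3g-%.3g), r^2 %.3g (%d pair(s) dropped)\n",
              x$rma_log10$slope, x$rma_log10$slope_ci[1], x$rma_log10$slope_ci[2],
              x$rma_log10$r_squared, x$n_dropped_log10))
  cat(sprintf("  average overestimation: %.1f%%\n", x$overestimation_percent))
  cat("  mean +/- sd (biomass mg C m^-3; volumetric PP mg C m^-3 d^-1):\n")
  m <- x$means
  for (s in rownames(m))
    cat(sprintf("    %-8s biomass %.3g +/- %.3g, PP %.3g +/- %.3g\n", s,
                m[s, "biomass_mean"], m[s, "biomass_sd"], m[s, "pp_mean"],
                m[s, "pp_sd"]))
  invisible(x)
}

#' @export
summary.cbpm_validation <- function(object, ...) object
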