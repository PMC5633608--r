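test_that("RMA point estimates match the moment oracle to 1e-12", {
  set.seed(42)
  # parameterised fixtures up to 20 points, positive and negative correlation
  cases <- list(
    list(x = rlnorm(10), noise = 0.3, b = 2.5),
    list(x = runif(20, 1, 9), noise = 0.8, b = -1.2),
    list(x = rnorm(7, 50, 4), noise = 2.0, b = 0.4)
  )
  for (cs in cases) {
    y <- cs$b * cs$x + rnorm(length(cs$x), sd = cs$noise)
    fit <- rma_fit(cs$x, y, ci_method = "analytic")
    # independent oracle: the stats-package composition of sd() and cor()
    r <- cor(cs$x, y)
    expect_equal(fit$slope, sign(r) * sd(y) / sd(cs$x), tolerance = 1e-12)
    expect_equal(fit$intercept, mean(y) - fit$slope * mean(cs$x),
                 tolerance = 1e-12)
    expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
    expect_equal(unname(coef(fit)), c(fit$intercept, fit$slope))
  }
})

test_that("a known scale fixture recovers slope s_y/s_x = 2.5", {
  # 10 points built so sample SDs are known by construction
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  y0 <- 2.5 * x
  y <- y0 + c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1) * 0.5
  fit <- rma_fit(x, y, ci_method = "analytic")
  expect_equal(fit$slope, sd(y) / sd(x), tolerance = 1e-12)
  expect_equal(fit$slope, 2.5, tolerance = 0.01)
})

test_that("exact linear data give slope 2, intercept 0, r^2 = 1", {
  x <- c(1, 3, 4, 7, 11)
  fit <- rma_fit(x, 2 * x, ci_method = "analytic")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), rep(0, 5), tolerance = 1e-12)
  expect_equal(predict(fit, c(5, 10)), c(10, 20), tolerance = 1e-12)
})

test_that("axis swap inverts the slope and scaling y is equivariant", {
  set.seed(7)
  x <- rlnorm(15); y <- 1.6 * x * exp(rnorm(15, 0, 0.2))
  f_xy <- rma_fit(x, y, ci_method = "analytic")
  f_yx <- rma_fit(y, x, ci_method = "analytic")
  expect_equal(f_yx$slope, 1 / f_xy$slope, tolerance = 1e-12)
  f_scaled <- rma_fit(x, 10 * y, ci_method = "analytic")
  expect_equal(f_scaled$slope, 10 * f_xy$slope, tolerance = 1e-12)
  # reordering the records changes nothing
  idx <- sample(15)
  f_perm <- rma_fit(x[idx], y[idx], ci_method = "analytic")
  expect_equal(f_perm$slope, f_xy$slope, tolerance = 1e-12)
  expect_equal(f_perm$intercept, f_xy$intercept, tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are refused", {
  expect_error(rma_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(rma_fit(c(1, 2, 3), c(5, 5, 5)), "degenerate")
  expect_error(rma_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bootstrap CIs are seeded, reproducible, and bracket the estimate", {
  set.seed(11)
  x <- rlnorm(40); y <- 1.7 * x * exp(rnorm(40, 0, 0.25))
  f1 <- rma_fit(x, y, seed = 99, nboot = 499)
  f2 <- rma_fit(x, y, seed = 99, nboot = 499)
  expect_identical(f1$slope_ci, f2$slope_ci)
  expect_identical(f1$intercept_ci, f2$intercept_ci)
  expect_true(f1$slope_ci[1] <= f1$slope && f1$slope <= f1$slope_ci[2])
  f3 <- rma_fit(x, y, seed = 100, nboot = 499)
  expect_false(identical(f1$slope_ci, f3$slope_ci))
  # the seeded bootstrap leaves the global RNG stream untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(rma_fit(x, y, seed = 3, nboot = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("log10 transform drops non-positive pairs with a count, fits on log scale", {
  x <- c(0, 0.5, 1, 2, 4, 8)
  y <- 2 * x
  expect_message(fit <- rma_fit(x, y, transform = "log10",
                                ci_method = "analytic"), "1 pair")
  expect_equal(fit$n, 5L)
  expect_equal(fit$n_dropped, 1L)
  # y = 2x is slope 1, intercept log10(2) on the log scale
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-12)
})

test_that("the formula interface matches the default method", {
  d <- data.frame(meas = c(1, 2, 4, 6), est = c(2.1, 3.9, 8.4, 11.6))
  f1 <- rma_fit(est ~ meas, data = d, ci_method = "analytic")
  f2 <- rma_fit(d$meas, d$est, ci_method = "analytic")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("self-consistent comparison returns slope 1, r^2 1, 0% overestimation", {
  cfg <- synthetic_config(n_stations = 30, seed = 21, bias = 1, noise_sigma = 0)
  st <- generate_stations(cfg)
  rep <- compare_to_measured(st, ci_method = "analytic")
  expect_equal(rep$rma_raw$slope, 1, tolerance = 1e-9)
  expect_equal(rep$rma_raw$intercept, 0, tolerance = 1e-9)
  expect_equal(rep$rma_raw$r_squared, 1, tolerance = 1e-9)
  expect_equal(rep$overestimation_percent, 0, tolerance = 1e-6)
  expect_equal(rep$rma_log10$slope, 1, tolerance = 1e-9)
  expect_error(compare_to_measured(st[1:2, ]), "at least 3")
})

test_that("comparison reports per-CCF-set means and overestimation consistent with slope", {
  cfg <- synthetic_config(n_stations = 60, seed = 31, bias = 1.5)
  st <- generate_stations(cfg)
  rep <- compare_to_measured(st, nboot = 199, seed = 31)
  expect_equal(rep$overestimation_percent, (rep$rma_raw$slope - 1) * 100,
               tolerance = 1e-12)
  expect_identical(rownames(rep$means), c("direct", "in_situ"))
  expect_true(all(rep$means[, "biomass_mean"] > 0))
  expect_equal(rep$n, 60L)
  # biomass means across sets differ only through the CCF averages
  ab <- colMeans(picoPP:::abundance_matrix_zero(st))
  expect_equal(unname(rep$means["direct", "biomass_mean"]),
               sum(ab * c(36, 255, 2590) * 1e-6), tolerance = 1e-12)
  expect_equal(unname(rep$means["in_situ", "biomass_mean"]),
               sum(ab * c(60, 154, 1319) * 1e-6), tolerance = 1e-12)
})
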