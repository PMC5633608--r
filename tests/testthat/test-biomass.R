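test_that("abundance-to-carbon conversion is the exact product rule", {
  expect_equal(biomass_from_abundance(4.8e3, 2590), 12.432, tolerance = 1e-12)
  expect_equal(biomass_from_abundance(1.5e3, 255), 0.3825, tolerance = 1e-12)
  expect_identical(biomass_from_abundance(0, 255), 0)
  # exact bilinearity
  for (a in c(10, 1e3, 7.7e5)) for (cc in c(16, 255, 4400)) {
    expect_equal(biomass_from_abundance(2 * a, cc),
                 2 * biomass_from_abundance(a, cc), tolerance = 1e-14)
    expect_equal(biomass_from_abundance(a, 2 * cc),
                 2 * biomass_from_abundance(a, cc), tolerance = 1e-14)
    expect_equal(biomass_from_abundance(a, cc), a * cc * 1e-6, tolerance = 1e-14)
  }
  expect_error(biomass_from_abundance(-1, 255), "non-negative")
  expect_error(biomass_from_abundance(10, 0), "positive")
})

test_that("CCF presets carry the published values and validate ordering", {
  direct <- ccf_table("direct")
  expect_equal(direct$average, c(36, 255, 2590))
  expect_equal(direct$min, c(16, 170, 800))
  expect_equal(direct$max, c(53, 350, 4400))
  expect_true(all(direct$min <= direct$average & direct$average <= direct$max))
  insitu <- ccf_table("in_situ")
  expect_equal(insitu$average, c(60, 154, 1319))
  expect_error(
    ccf_table("custom", values = data.frame(
      min = c(-5, 170, 800), max = c(53, 350, 4400), average = c(36, 255, 2590),
      row.names = c("prochlorococcus", "synechococcus", "picoeukaryotes"))),
    "CCF table invalid")
  # shipped files mirror the in-code presets
  expect_equal(
    as.data.frame(read_ccf_table(system.file("extdata", "ccf_direct.yml",
                                             package = "picoPP"))),
    as.data.frame(direct))
})

test_that("station biomass treats absent groups as zero and sums to total", {
  b <- biomass_station(list(syn_cells_ml = 2.2e4, euk_cells_ml = 4.8e3),
                       ccf_table("direct"))
  expect_equal(unname(b["synechococcus"]), 5.61, tolerance = 1e-12)
  expect_equal(unname(b["picoeukaryotes"]), 12.432, tolerance = 1e-12)
  expect_identical(unname(b["prochlorococcus"]), 0)
  expect_equal(unname(b["total"]), sum(b[c("prochlorococcus", "synechococcus",
                                           "picoeukaryotes")]))
  expect_identical(attr(b, "missing_groups"), "prochlorococcus")
  zero <- biomass_station(list(pro_cells_ml = 0, syn_cells_ml = 0,
                               euk_cells_ml = 0), ccf_table("direct"))
  expect_true(all(zero == 0))
  # monotonicity across the CCF columns
  rec <- list(pro_cells_ml = 1e4, syn_cells_ml = 2e4, euk_cells_ml = 3e3)
  expect_true(biomass_station(rec, which = "max")["total"] >=
                biomass_station(rec, which = "min")["total"])
})

test_that("CCF sensitivity grid has 11 inclusive levels with exact max/min ratios", {
  recs <- demo_stations()
  sens <- ccf_sensitivity(recs, ccf_table("direct"), mode = "joint")
  expect_equal(sort(unique(sens$summary$level_percent)), seq(0, 100, by = 10))
  expect_equal(nrow(sens$levels), 11L)
  expect_equal(sens$levels[1, ], c(prochlorococcus = 16, synechococcus = 170,
                                   picoeukaryotes = 800))
  expect_equal(sens$levels[11, ], c(prochlorococcus = 53, synechococcus = 350,
                                    picoeukaryotes = 4400))
  # mean PP is linear in the CCF, so the 100%:0% ratio is exactly max/min
  med <- sens$summary[sens$summary$statistic == "mean", ]
  ratio <- function(g) med$value[med$group == g & med$level_percent == 100] /
    med$value[med$group == g & med$level_percent == 0]
  expect_equal(ratio("picoeukaryotes"), 4400 / 800, tolerance = 1e-12)
  expect_equal(ratio("synechococcus"), 350 / 170, tolerance = 1e-12)
  expect_equal(ratio("prochlorococcus"), 53 / 16, tolerance = 1e-12)
  # monotone non-decreasing in level for every group and statistic
  for (g in unique(sens$summary$group)) for (s in c("median", "mean")) {
    v <- sens$summary$value[sens$summary$group == g & sens$summary$statistic == s]
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("per-group sensitivity varies one CCF at a time against average others", {
  recs <- demo_stations()
  sens <- ccf_sensitivity(recs, mode = "per_group")
  expect_equal(nrow(sens$summary[sens$summary$statistic == "median", ]), 3L * 11L)
  # a picoeukaryote-only record set: total PP scales exactly with the Euk CCF
  euk_only <- data.frame(sst_c = 20, chl_mgm3 = 2, euk_cells_ml = 5e3)
  s2 <- ccf_sensitivity(euk_only, mode = "per_group")
  med <- s2$summary[s2$summary$statistic == "median" &
                      s2$summary$group == "picoeukaryotes", ]
  expect_equal(med$value[med$level_percent == 100] /
                 med$value[med$level_percent == 0], 5.5, tolerance = 1e-12)
  # single record + single group: PP is exactly linear in the CCF level
  fit <- stats::lm(value ~ level_percent, data = med)
  expect_equal(unname(max(abs(stats::residuals(fit)))), 0, tolerance = 1e-12)
  expect_error(ccf_sensitivity(demo_stations()[0, ]), "at least one")
})

test_that("the two shipped CCF sets differ on identical records by the CCF ratios only", {
  recs <- demo_stations()
  fit_d <- cbpm(recs, ccf = "direct", integrate = FALSE)$estimates
  fit_i <- cbpm(recs, ccf = "in_situ", integrate = FALSE)$estimates
  expect_equal(fit_i$pp_vol_syn / fit_d$pp_vol_syn, rep(154 / 255, 3),
               tolerance = 1e-12)
  expect_equal(fit_i$pp_vol_euk / fit_d$pp_vol_euk, rep(1319 / 2590, 3),
               tolerance = 1e-12)
})
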