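# shared fixture: a small hand-built station table exercising every column
demo_stations <- function() {
  data.frame(
    lat = c(38.5, 39.1, 40.0), lon = c(119.2, 120.0, 118.4),
    date = c("2005-06-25", "2005-06-25", "2005-06-26"),
    sst_c = c(21.1, 18.4, 24.0),
    chl_mgm3 = c(4.7, 3.1, 0.3),
    par_mol_m2_d = c(49.3, 45.0, 50.2),
    k490_m1 = c(0.3, 0.25, NA),
    zeu_m = c(15.1, NA, 12.0),
    pro_cells_ml = c(NA, 0, 1.2e4),
    syn_cells_ml = c(2.2e4, 1.1e4, 3.0e4),
    euk_cells_ml = c(4.8e3, 2.0e3, 6.5e3),
    pp14c = c(5.2, 2.1, 9.8)
  )
}

# independent growth oracles evaluated straight from the published equations
oracle_mu_syn <- function(tc) exp(-0.73 / (8.62e-5 * (tc + 273.15)) + 28.13)
oracle_mu_euk <- function(tc) exp(-0.86 / (8.62e-5 * (tc + 273.15)) + 33.85)
oracle_mu_mit <- function(tc) -4.17 + 0.40 * tc - 0.0086 * tc^2
oracle_mu_med <- function(tc) -1.11 + 0.14 * tc - 0.0035 * tc^2
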