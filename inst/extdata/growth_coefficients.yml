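# Temperature-growth coefficients for picophytoplankton groups.
# Prochlorococcus: mu = a0 + a1*T + a2*T^2          (T in degrees Celsius)
# Synechococcus / picoeukaryotes: ln(mu) = -E/(k*T_K) + intercept
#   with E in eV, k = 8.62e-5 eV/K, T_K in kelvin.
version: 1
prochlorococcus:
  eMIT9312: {a0: -4.17, a1: 0.40, a2: -0.0086}
  eMED4: {a0: -1.11, a1: 0.14, a2: -0.0035}
synechococcus:
  activation_energy_ev: 0.73
  ci_activation_energy: [0.60, 0.88]
  intercept_ln_mu_c: 28.13
  ci_intercept: [23.20, 34.15]
  fit_range_c: [10, 34]
picoeukaryotes:
  activation_energy_ev: 0.86
  ci_activation_energy: [0.68, 1.07]
  intercept_ln_mu_c: 33.85
  ci_intercept: [26.94, 42.35]
  chl_threshold_mg_m3: 0.5
  low_chl_bias_divisor: 1.58
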