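---
title: "Carbon-based modelling of picophytoplankton production: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-based modelling of picophytoplankton production: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoPP)
```

## The model

Primary production of the three marine picophytoplankton groups —
*Prochlorococcus*, *Synechococcus* and picoeukaryotes — is estimated from
standing stock and growth rather than from chlorophyll. For each group the
depth-integrated production (mg C m⁻² d⁻¹) is

$$PP = C \times \mu \times Z_{eu} \times h(I_0)$$

where $C$ is the surface-layer carbon biomass (mg C m⁻³), $\mu$ the specific
growth rate (d⁻¹), $Z_{eu}$ the euphotic depth (m), and $h(I_0)$ a
dimensionless factor describing how surface irradiance shapes the
depth-dependent carbon-fixation profile. Dropping the last two factors gives
the volumetric form $PP = C\mu$ (mg C m⁻³ d⁻¹), the scale on which measured
¹⁴C uptake rates are reported and the pathway `compare_to_measured()` uses.

The surface layer drives the whole column: no vertical structure in $C$ or
$\mu$ is modelled. This matches the empirical observation, in the shelf-sea
application the seasonal fixtures emulate, that picophytoplankton abundance
shows no significant depth dependence within the sampled layers.

### Carbon biomass

$C$ is cell abundance (cells mL⁻¹, from flow cytometry) times a fixed
cellular carbon conversion factor (CCF, fg C cell⁻¹):
$C = A \cdot \mathrm{CCF} \cdot 10^{-6}$, the $10^{-6}$ converting
fg mL⁻¹ to mg m⁻³ (1 m³ = 10⁶ mL, 1 fg = 10⁻¹⁵ g = 10⁻¹² mg). Two compiled
CCF sets ship with the package:

| group | direct (min / max / avg) | in-situ avg |
|---|---|---|
| *Prochlorococcus* | 16 / 53 / 36 | 60 |
| *Synechococcus* | 170 / 350 / 255 | 154 |
| picoeukaryotes | 800 / 4400 / 2590 | 1319 |

The `direct` set comes from unialgal culture measurements and is the default;
the `in_situ` set was derived from flow-cytometric cell size and
carbon:volume relationships. Only averages were reported for the in-situ set,
so its min/max span retains the culture compilation's bounds (this matters
only for sensitivity sweeps run on that set).

### Growth rates

*Prochlorococcus*: concave-down binomial polynomials
$\mu = a_0 + a_1 T + a_2 T^2$ in Celsius for the two high-light-adapted
ecotypes, eMIT9312 ($-4.17 + 0.40T - 0.0086T^2$) and eMED4
($-1.11 + 0.14T - 0.0035T^2$). Arrhenius kinetics do not fit these curves,
which peak near 23 °C and 20 °C respectively and go negative in cold water.
Negative values are clamped to zero and flagged (`clamped`) rather than
refused: cold-season coastal records would otherwise yield negative
production. Because no mixing rule exists for field populations in which
both ecotypes occur, the default `ecotype = "mean"` averages the two
polynomials before clamping; either ecotype can be selected explicitly.

*Synechococcus* and picoeukaryotes: Arrhenius forms
$\ln\mu = -E/(kT_K) + b$ with $k = 8.62\times10^{-5}$ eV K⁻¹ and
$T_K = T(°C) + 273.15$ (the conversion offset is the package's choice; only
the kelvin form of the equation is published). Coefficients:
$E = 0.73$ eV, $b = 28.13$ for *Synechococcus* (culture data, fitted over
10–34 °C); $E = 0.86$ eV, $b = 33.85$ for the picoeukaryote community (field
data restricted to total chlorophyll > 0.5 mg m⁻³, since the community is
taxonomically too diverse for any single culture curve).

Two advisory flags keep the model's validity envelope visible without
blocking computation:

* `extrapolated` — *Synechococcus* evaluated outside 10–34 °C. The seasonal
  shelf-sea application itself does this (5.9 °C in March), so extrapolation
  is permitted by design, flagged per record.
* `low_chl_warning` — picoeukaryote rate evaluated below 0.5 mg m⁻³ total
  chlorophyll, where the temperature relationship is not significant and the
  fitted curve overestimates growth by roughly 58 % on average. No
  alternative model exists for that regime, so the equation is still applied;
  `bias_correct = TRUE` divides flagged rates by 1.58 as an optional crude
  correction (off by default, since the correction is an average, not a
  model).

Coefficients ship both in code (`growth_params()`) and as a versioned YAML
file (`inst/extdata/growth_coefficients.yml`) that users can copy, edit and
load with `read_growth_params()`.

### Light field

$Z_{eu} = -\ln(0.01)/k_{490}$, the 1 %-light depth under exponential
attenuation. As printed in its source the formula carries a sign that would
make the depth negative; it is implemented with the sign fixed so that
$Z_{eu} \cdot k_{490} = 4.60517\ldots$ exactly. That relation was derived for
oligotrophic and upwelling water and overestimates $Z_{eu}$ in turbid coastal
water, so when a record carries an externally supplied euphotic depth (e.g. a
satellite product based on inherent optical properties) that value wins under
the default `zeu_source = "auto"`; `"formula"` and `"external"` force either
source.

$h(I_0) = 0.66125\, I_0/(I_0 + 4.1)$, monotone, concave, saturating below
0.66125, half-saturated at $I_0 = 4.1$. $I_0$ is fixed as **daily** PAR
(mol photons m⁻² d⁻¹) throughout: the half-saturation constant and the
seasonal values the model is applied at (16–49 mol photons m⁻² d⁻¹) are only
consistent with daily units, although an hourly unit appears once in the
source material's text. The column name `par_mol_m2_d` makes the convention
explicit.

## Reduced major axis validation

Model estimates and measured ¹⁴C rates both carry error, so ordinary least
squares would attenuate the comparison slope; `rma_fit()` implements the
reduced major axis (Model II) estimator, slope $= \mathrm{sign}(r)\,s_y/s_x$,
intercept $= \bar y - b\bar x$, with $r^2$ the squared Pearson correlation on
the fitted scale. Fits are reported on the raw and the log₁₀ scale;
non-positive pairs are dropped from the log fit with a count, never silently.
The raw-scale slope minus one is reported as the model's average
overestimation percentage.

Confidence intervals: the CI method behind the published comparison is
unstated, so the default here is a seeded bias-corrected percentile bootstrap
(1999 paired resamples), robust to the heavy-tailed production distributions
involved; the closed-form interval
$b(\sqrt{B+1} \pm \sqrt{B})$, $B = t^2_{\alpha/2, n-2}(1-r^2)/(n-2)$, is
available as `ci_method = "analytic"` and is what the fast tests use. The
bootstrap restores the caller's RNG state, so seeding a fit never perturbs a
surrounding simulation.

## The synthetic generator

`generate_stations()` emulates an open-ocean compilation of paired
flow-cytometry and ¹⁴C stations; `bohai_fixture()` emulates one season of a
temperate shelf-sea campaign. Defaults were fixed once, on field-plausibility
grounds:

* SST uniform on −1…29 °C (polar to tropical surface water); chlorophyll
  log-normal, median 0.3 mg m⁻³, geometric SD 3 (oligotrophic to
  mesotrophic); daily PAR uniform on 15–55 mol photons m⁻² d⁻¹; $k_{490}$
  log-normal, median 0.06 m⁻¹.
* Abundances log-normal (field abundances span 10²–10⁶ cells mL⁻¹, so
  additive Gaussian noise would be unfaithful): medians 5×10⁴ / 10⁴ / 2×10³
  cells mL⁻¹ for Pro / Syn / Euk with geometric SDs 4 / 3 / 3, and
  *Prochlorococcus* present at a station with probability 0.7 (it is absent
  from cold and coastal water).
* The synthetic "measured" rate is
  $PP_{14C} = PP_{model} / b \cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$: the bias $b$ sits on the measured side
  so that the generating estimated:measured slope is $b$ by construction.
  Default $\sigma = 0.25$, i.e. a ~25 % coefficient of variation,
  representing replicate measurement uncertainty of ¹⁴C incubations.

The shelf-sea fixtures draw environment variables from truncated Gaussians
(resampling any non-positive draw) around each season's published mean ± SD,
abundances from log-normals matching the seasonal mean and SD, and set
*Prochlorococcus* to zero everywhere, as observed in that sea. They are
synthetic stand-ins for unpublished per-station data: only distributional
summaries are faithful, so tests against them check orders of magnitude, not
station values.

### What passing tests do and do not show

The generator models *measurement* error only. Real model-vs-field
comparisons also contain structural error — invariant CCFs, growth curves
from a handful of strains, no light or nutrient limitation of growth — which
is why field comparisons scatter far more (raw $r^2 \approx 0.5$) than
synthetic ones (raw $r^2 \approx 0.9$ at default noise). This is a deliberate
design point, not an oversight: with one-sided multiplicative noise the RMA
slope is attenuated below the true bias by the factor
$r\,e^{-\sigma^2/2}$ for log-normal production, so no one-sided noise level
can simultaneously reproduce the field scatter and return the injected bias
exactly. At the default measurement-noise level the 200-replicate recovery
experiment returns a median slope within 10 % of an injected 1.7-fold bias;
at field-like scatter it would not, and a validation exercise on real data
should interpret the RMA slope with that attenuation in mind.

## Numerical and interface choices

* All growth results are vectorised data frames carrying `mu` plus the three
  flags; flags propagate through `cbpm()` into the per-station output, and
  the CLI logs them at station granularity, so cold-season clamping and
  low-chlorophyll regimes are visible in every artefact.
* Missing abundance columns (or empty cells) contribute zero biomass with a
  per-group `flag_*_missing` provenance column — absence of a group is data,
  not an error. Missing temperature, or missing both $k_{490}$ and external
  $Z_{eu}$ when integration is requested, is an error.
* The CCF sensitivity grid is inclusive: levels $\mathrm{min} + j/10 \cdot
  (\mathrm{max}-\mathrm{min})$, $j = 0..10$, 11 levels. `"joint"` mode (the
  default) moves all groups together; `"per_group"` varies one group with the
  others at their averages. Because volumetric production is linear in the
  CCF, the mean-PP ratio between the top and bottom levels equals the
  max/min CCF ratio exactly (5.5, 3.3125, ~2.06 for Euk / Pro / Syn); the
  median ratio matches only when the median station has non-zero production
  for that group.
* One canonical CSV schema with units in the column names
  (`sst_c`, `chl_mgm3`, `par_mol_m2_d`, `k490_m1`, `zeu_m`, `*_cells_ml`,
  `pp14c`); empty cell = missing, no sentinel numbers; unknown columns are a
  schema error so that derived outputs cannot be silently re-ingested.
* Every CLI output carries a `.meta.json` sidecar with package version, seed
  and a hash of the resolved configuration, making runs replayable from the
  sidecar alone.

### Problem sizes

The test suite and acceptance script use sizes chosen to make the statistics
stable while staying desk-scale: 171 stations per synthetic campaign
(matching the size of the published field compilation), 200 replicates for
the slope-recovery experiment, 10⁴ stations for the law-of-large-numbers
check on the generator, 50 stations per seasonal fixture, and 99–999
bootstrap resamples in tests (1999 at the user-facing default).

## Known limitations

* Growth depends on temperature only; light and nutrient limitation of
  growth are out of scope, as is any re-fitting of the growth–temperature
  curves to new culture data.
* CCFs are invariant per group; cell-size-based allometric carbon estimation
  is out of scope.
* The picoeukaryote model below 0.5 mg m⁻³ chlorophyll is an extrapolation
  with a known average bias; the flag (and optional divisor) is the only
  mitigation offered.
* The seasonal fixtures reproduce summary statistics, not the spatial
  structure, of a real campaign: no spatial autocorrelation, pixel geometry
  or seasonal succession is emulated.
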