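# picoPP — carbon-based picophytoplankton productivity modelling

Marine picophytoplankton — *Prochlorococcus*, *Synechococcus* and the
picoeukaryotes — contribute a large share of oceanic primary production, but
measuring their production directly (¹⁴C incubations) is too slow and
labour-intensive for basin-scale surveys. What *is* routinely measured at
scale is their cell abundance, by flow cytometry. **picoPP** implements a
carbon-based productivity model that turns those abundances into
group-specific production estimates:

```
PP = C × μ × Z_eu × h(I₀)        (depth-integrated, mg C m⁻² d⁻¹)
PP = C × μ                       (volumetric, mg C m⁻³ d⁻¹)
```

where

- `C = abundance × CCF × 10⁻⁶` is carbon biomass (mg C m⁻³), with CCF the
  cellular carbon content in fg C cell⁻¹ (shipped presets: culture-derived
  averages 36 / 255 / 2590 and in-situ averages 60 / 154 / 1319 for
  Pro / Syn / Euk);
- `μ` is a temperature-dependent growth rate (d⁻¹): concave binomial
  polynomials per *Prochlorococcus* ecotype, Arrhenius forms
  `ln μ = −E/(kT) + b` for *Synechococcus* (E = 0.73 eV) and picoeukaryotes
  (E = 0.86 eV), with `k = 8.62 × 10⁻⁵ eV K⁻¹`;
- `Z_eu = −ln(0.01)/k490` is the euphotic depth (m), overridable by an
  external inherent-optical-properties product in turbid coastal water;
- `h(I₀) = 0.66125 I₀/(I₀ + 4.1)` is the saturating surface-irradiance term
  (I₀ in mol photons m⁻² d⁻¹).

The package is intended for biological oceanographers who have per-station
cytometry + remote-sensing environment tables and want production estimates,
a carbon-conversion-factor sensitivity analysis, and a Model II
(reduced major axis) validation against whatever measured ¹⁴C rates exist.

## Worked example

A June shelf-sea station (21.1 °C, Chl 4.7 mg m⁻³, PAR 49.3, external
Z_eu 15.1 m, 2.2 × 10⁴ *Synechococcus* and 4.8 × 10³ picoeukaryote
cells mL⁻¹; *Prochlorococcus* not detected):

```r
library(picoPP)
rec <- list(sst_c = 21.1, chl_mgm3 = 4.7, par_mol_m2_d = 49.3, zeu_m = 15.1,
            syn_cells_ml = 2.2e4, euk_cells_ml = 4.8e3)
estimate_station(rec)
#> Picophytoplankton production estimate (Z_eu source: external_iop)
#>                                   Pro     Syn      Euk    total
#> mu (d^-1)                      0.3635  0.5218   0.9457       NA
#> volumetric PP (mg C m^-3 d^-1) 0.0000  2.9271  11.7566  14.6837
#> integrated PP (mg C m^-2 d^-1) 0.0000 26.9824 108.3756 135.3579
#> groups absent (treated as zero): prochlorococcus
```

Reading the output: *Synechococcus* grows at 0.52 d⁻¹ at 21.1 °C and its
5.6 mg C m⁻³ of biomass fixes ~2.9 mg C m⁻³ d⁻¹; integrated over the 15.1 m
euphotic column with `h(49.3) = 0.61` that is ~27 mg C m⁻² d⁻¹. The
picoeukaryotes, though fewer, carry a far larger per-cell carbon content and
dominate the total of ~135 mg C m⁻² d⁻¹.

Validation against (here: synthetic) measured rates with a known 1.7-fold
model bias:

```r
st <- generate_stations(synthetic_config(n_stations = 171, seed = 2, bias = 1.7))
compare_to_measured(st, nboot = 999, seed = 2)
#> Validation of carbon-based production against measured 14C uptake
#>   n = 171  (regression CCF set: direct )
#>   raw scale:   slope 1.76 (CI 1.31-1.9), intercept -0.718, r^2 0.948
#>   log10 scale: slope 0.991 (CI 0.969-1.02), r^2 0.976 (0 pair(s) dropped)
#>   average overestimation: 76.2%
#>   mean +/- sd (biomass mg C m^-3; volumetric PP mg C m^-3 d^-1):
#>     direct   biomass 19.5 +/- 21.4, PP 11.1 +/- 24.5
#>     in_situ  biomass 15 +/- 15.7, PP 6.52 +/- 12.8
```

The reduced-major-axis slope of estimated on measured production (1.76 here)
estimates the model's multiplicative bias; `(slope − 1) × 100` is the average
overestimation percentage.

Other entry points: `cbpm()` (whole station tables, returns a classed fit
with `summary`/`plot` methods), `ccf_sensitivity()` (11-level CCF sweep),
`bohai_fixture()` (seasonal shelf-sea fixtures), `rma_fit()` (standalone
Model II regression with bootstrap CIs), and `read_stations()` /
`write_stations()` for the canonical station CSV schema.

## Command line

```sh
exec/picopp simulate --season June --n 50 --seed 7 --output june.csv
exec/picopp estimate --input june.csv --output june_pp.csv
exec/picopp sensitivity --input june.csv --output sens.csv --mode joint
exec/picopp validate --input campaign.csv --output report --resamples 1999
```

Every output gets a `.meta.json` sidecar (package version, seed, config
hash) so any run can be replayed.

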