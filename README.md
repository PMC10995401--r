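# transloc

Free-energy analysis of peptide translocation across symmetric and
asymmetric lipid membranes.

Antimicrobial and cell-penetrating peptides cross lipid bilayers over
large free-energy barriers. For an *asymmetric* bilayer — different
lipids, or different lipid numbers, in the two leaflets — the
translocation free-energy profile G(ξ) is direction-dependent: the
barrier the peptide must climb depends on which leaflet it inserts
from, and the widely used serial-resistance estimate
1/P<sub>AB</sub> = 1/P<sub>A</sub> + 1/P<sub>B</sub> can fail badly
because it is blind to direction. `transloc` provides the full analysis
chain used in such studies, for R:

- **WHAM** — a self-consistent weighted-histogram solver that unbiases
  umbrella-sampling window timeseries into G(ξ), with window-overlap
  diagnostics and moving-block bootstrap error bands;
- **profile assembly** — least-squares alignment and joining of
  translocation subprocess profiles (adsorption/insertion × terminus ×
  leaflet) into full directional paths, plus hysteresis-style
  comparisons;
- **region classification** — decomposition of an asymmetric-membrane
  profile into two *mimicking* regions (indistinguishable from the
  corresponding pure membranes within a threshold) and an
  *intermediate* region;
- **transport models** — directional translocation barriers
  ΔΔG<sub>B</sub> (the largest climb from a preceding minimum to a later
  maximum along the crossing direction), relative permeabilities
  P ∝ exp(−ΔΔG<sub>B</sub>/kT), the serial-resistance model, a corrected
  barrier estimator built from pure-membrane profiles, and an exact
  solubility-diffusion reference;
- **membrane mechanics** — lateral/normal pressures from stress-tensor
  profiles (P<sub>L</sub> = −(σ<sub>xx</sub>+σ<sub>yy</sub>)/2,
  P<sub>N</sub> = −σ<sub>zz</sub>), midplane location from lipid tail
  densities, and leaflet tensions γ± = ∫ (P<sub>N</sub>−P<sub>L</sub>) dz
  over each half-space;
- **synthetic ground truth** — parametric translocation landscapes,
  tiered umbrella-window schemes, reproducible biased Boltzmann
  sampling, and stress profiles with closed-form leaflet tensions, so
  every stage of the chain can be validated against known answers
  without molecular-dynamics trajectories.

Everything is tidyverse-native: functions take and return tibbles,
fitted objects support `tidy()`/`glance()`, and every result type has an
`autoplot()` or `plot_*()` method.

## Worked example

Recover a double-well translocation landscape (adsorption minima of
−40 kJ/mol at ±2 nm, central barrier of +150 kJ/mol) from biased
sampling with production-style window tiers, then read off the
directional barriers of an asymmetric landscape:

```r
library(transloc)

# ground truth and a tiered umbrella-window scheme
L <- pmf_landscape(well_depth = 40, center_G = 150)
scheme <- window_scheme(c(-4.5, 4.5), center_band = c(-0.8, 0.8),
                        surface_band = list(c(-4.5, -1.6), c(1.6, 4.5)),
                        spacing_surface = 0.1, spacing_center = 0.05)

# biased sampling and WHAM
ts <- sample_windows(L, scheme, sampler_params(n_steps = 20000,
                                               n_equil = 1000), seed = 1)
settings <- wham_settings()
fit <- solve_wham(histogram_windows(ts, settings), scheme, settings,
                  reference_region = c(4.0, 4.5))
compare_profiles(fit$profile, landscape_profile(L),
                 region = c(-4.3, 4.3), ref_region = c(4.0, 4.5))
#> # A tibble: 1 × 3
#>   max_abs_dev  rmsd     n
#>         <dbl> <dbl> <int>
#> 1        1.14 0.432   430
```

The 150 kJ/mol barrier landscape is recovered with an RMS deviation of
about 0.4 kJ/mol. Directional barriers of an asymmetric membrane whose
leaflets adsorb the peptide with different strength (−40 vs −10 kJ/mol):

```r
up <- pmf_landscape(well_depth = 40, center_G = 150)
lo <- pmf_landscape(well_depth = 10, center_G = 150)
asym <- landscape_profile(blend_landscapes(up, lo, blend_spec(0, 0.1)))
model_comparison(asym, landscape_profile(up), landscape_profile(lo))[,
  c("direction", "ddG_true", "ddG_serial", "ddG_estimator")]
#> # A tibble: 2 × 4
#>   direction    ddG_true ddG_serial ddG_estimator
#>   <chr>           <dbl>      <dbl>         <dbl>
#> 1 upper->lower     190.       188.          190.
#> 2 lower->upper     160.       188.          160.
```

The two directions differ by the 30 kJ/mol adsorbed-state difference;
the serial-resistance model gives one direction-independent number
(188 kJ/mol, essentially the larger barrier), while the corrected
estimator — average of the pure-membrane maxima minus the entry-side
adsorbed minimum — tracks each direction to within a fraction of a
kJ/mol here.

A command-line wrapper over the same functions is installed at
`inst/scripts/transloc` (subcommands `simulate`, `wham`, `regions`,
`barriers`, `tension`, `demo`).

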