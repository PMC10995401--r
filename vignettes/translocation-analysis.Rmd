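---
title: "Free-energy analysis of peptide translocation across asymmetric membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy analysis of peptide translocation across asymmetric membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transloc)
```

## The problem

A peptide crossing a lipid bilayer passes through a sequence of states:
dissolved in water (state 1), adsorbed flat on the membrane surface
(2a), one terminus inserted (3a), and a transmembrane configuration
(4a), before leaving on the far side. The free energy G along a
collective variable ξ — here the oriented z-distance between a probe
group's center of mass (e.g. the three terminal backbone beads of a
peptide) and the *local* membrane center of mass, computed from lipid
beads inside a 2.0 nm cylinder around the probe — quantifies this
process: a solvent plateau (the gauge zero), adsorption minima of tens
of kJ/mol, and a central barrier that can exceed 150 kJ/mol.

For an asymmetric bilayer the profile is no longer symmetric, and the
translocation barrier depends on the crossing direction and on which
terminus inserts first. This package implements the full analysis chain
for such profiles, and a synthetic-data layer that lets every stage be
validated against analytically known ground truth.

## Synthetic landscapes and biased sampling

`pmf_landscape()` builds G(z) as a sum of symmetric Gaussian features —
paired adsorption wells, optional paired headgroup barriers and a
central barrier — on top of a solvent plateau. Profiles of this shape
are what coarse-grained peptide translocation calculations produce, and
a Gaussian basis has two properties we rely on: it is smooth with a
closed-form derivative (needed by the Langevin sampler), and its
amplitudes can be solved linearly so the requested control-point values
(`G(well_pos) = plateau − well_depth`, `G(0) = center_G`) hold exactly,
which makes downstream tolerances meaningful. A C¹ taper forces G to
the plateau exactly beyond the solvent boundary (default 4.0 nm), so the
reference region is exactly flat.

Asymmetric-membrane landscapes are built by `blend_landscapes()`: a
pointwise convex combination of two pure-membrane landscapes with a
sigmoid weight w(z) = 1/(1 + exp((z − z_c)/λ)). This realizes the
empirical structure of asymmetric profiles — coinciding with one pure
membrane near each leaflet, with a gradual transition of width λ around
the switch center — while keeping the truth analytic.

`window_scheme()` lays out umbrella windows in tiers, following the
production convention for translocation runs: 0.1 nm spacing with
1000 kJ mol⁻¹ nm⁻² springs near the membrane surface, 0.05 nm with
5000 kJ mol⁻¹ nm⁻² near the center where the profile is steepest, and
3000 kJ mol⁻¹ nm⁻² in between. Bands are explicit parameters rather
than hard-coded per-membrane layouts, since exact window counts vary
with membrane thickness.

`sample_window()` draws a reproducible Markov chain from the biased
Boltzmann density ∝ exp(−U(z)/kT), U(z) = G(z) + (k/2)(z − z₀)². The
default scheme is random-walk Metropolis, whose stationary distribution
is *exactly* the target at any step size — the right property for
validating an unbiasing estimator, where a discretization bias in the
sampler would be indistinguishable from a solver defect. An
Euler–Maruyama overdamped-Langevin scheme is also provided
(`scheme = "overdamped-langevin"`); it carries an O(dt) stationary bias
and refuses to run when the per-step drift exceeds half a nanometre,
suggesting a smaller dt. The Metropolis proposal width defaults to
2·sqrt(kT/k), which keeps acceptance rates in a healthy range across
the force-constant tiers. The potential is tabulated on a 5·10⁻⁴ nm
grid and interpolated linearly inside the compiled samplers; the
associated error in G is ~10⁻⁵ kJ/mol, far below every tolerance used.

All free energies are in kJ/mol and kT = 0.0083145 · 310 ≈ 2.577 kJ/mol
throughout: translocation free-energy surfaces of this kind are
computed at physiological 310 K.

The generator emulates the *shape* of real data — tiered windows,
correlated in-window timeseries, an equilibration stretch to discard —
but not everything real trajectories contain: there is no slow
orthogonal relaxation (peptide reorientation, membrane deformation), no
hidden hysteresis between window-generation protocols, and the true
landscape is exactly one-dimensional. Passing tests therefore certify
the estimators, not the convergence of any particular simulation.

## WHAM

`solve_wham()` iterates the coupled weighted-histogram equations

  p_j = M_j / Σ_i N_i exp((f_i − U_i(z_j))/kT),
  f_i = −kT log Σ_j p_j exp(−U_i(z_j)/kT)

until the largest change in any window constant f_i falls below `tol`
(default 10⁻⁶ kJ/mol — a scale-aware criterion, since the f_i are free
energies). Each window's bias column is shifted by its minimum before
exponentiation, which cancels exactly in the update and keeps the
arithmetic in range even for 5000 kJ mol⁻¹ nm⁻² springs far from their
anchor. Bins are half-open `[lo, hi)` of width 0.02 nm by default — at
most half the finest window spacing, so windows are resolved without
starving bins of counts. Disconnected window sets (no shared nonzero
bin along some cut) are refused with the components listed, because the
relative offset of disconnected groups is not identifiable.

The profile is reported as G = −kT log p, anchored so the *mean* over a
declared solvent region is zero (default: the outermost 0.5 nm at the
upper end of the sampled range). Anchoring on a region average rather
than a single bin keeps the gauge stable under resampling.

Errors come from `bootstrap_error()`: a moving-block bootstrap within
each window, with block length 2·τ_int estimated from the chain's
autocorrelation (capped at a tenth of the chain), re-solving WHAM per
replicate (warm-started from the base solution) and taking pointwise
standard deviations after re-anchoring each replicate. The error method
for published profiles of this kind is typically unstated; this
bootstrap is a documented stand-in, not a reproduction of any
particular choice.

The test suite cross-checks the solver against an independent
formulation — direct minimization of the WHAM negative log-likelihood
over the window constants — and requires agreement to 0.05 kJ/mol on
identical histograms.

## Assembling full translocation paths

Production translocation profiles are assembled from eight subprocess
calculations (adsorption and insertion, for each terminus and each
leaflet), each converged separately and therefore carrying an arbitrary
additive constant. `join_translocation()` maps the four segments of one
directional path onto a single path coordinate — entry-side solvent
positive, membrane center at 0, exit-side segments reversed and
sign-flipped — and removes the constants by least-squares alignment
over declared overlap intervals: the offset minimizing the mean squared
difference over an overlap is the mean difference there, a unique
closed form that is exactly gauge-correct. The default overlaps are the
central 0.3 nm of each pairwise range intersection (the
adsorbed-minimum and transmembrane-state neighbourhoods); they are
configurable because the optimal choice depends on where segments are
well converged. Interpolation is monotone (Fritsch–Carlson) cubic on G
— no overshoot at sharp barriers — and linear on the error band.

The alignment procedure used for the published profiles this mirrors is
described only in supplementary material we treat as unavailable; the
least-squares-on-overlaps rule is this package's own documented choice,
with the reassembly identity (cut any continuous profile into four
shifted segments, rejoin, recover to 10⁻⁹ kJ/mol) as its correctness
criterion.

`compare_profiles()` supports hysteresis-style checks: both inputs are
independently re-anchored over the same region, so only shape
differences are reported.

## Mimicking and intermediate regions

`classify_regions()` decomposes an asymmetric profile against its two
pure-membrane parents: the *mimicking* intervals are the maximal
contiguous runs inward from each solvent end with
|G_asym − G_pure| ≤ threshold, and the remainder is the *intermediate*
region. The default threshold of 5 kJ/mol is the working error level of
converged coarse-grained translocation profiles; when both sweeps claim
overlapping territory (e.g. the shared solvent plateau of very similar
parents) the boundary is placed at the midpoint of the overlap so the
three intervals always partition the range. On blended synthetic
landscapes the intermediate width grows strictly with the blend width λ,
which the acceptance tests assert over five λ values.

## Barriers and permeability models

`directional_barrier()` computes ΔΔG_B as the largest climb along the
travel direction — max over z of G(z) minus the running minimum of G up
to z — and reports the achieving minimum/maximum pair. A profile that
never climbs yields 0 with a flag rather than an error. This definition
makes barriers direction-specific in asymmetric membranes.

Permeability is reported on a relative scale, P = exp(−ΔΔG_B/kT) with
the proportionality constant fixed to 1; only ratios and model
discrepancies are meaningful. The temperature convention inside the
exponential is per-molecule kT at 310 K; published barrier-to-
permeability ratios are convention-dependent (kT vs RT is often left
implicit), so the constant is documented here rather than asserted.

Two estimates of an asymmetric membrane's barrier are compared with the
truth in `model_comparison()`:

* the **serial-resistance model**, 1/P_AB = 1/P_A + 1/P_B, with leaflet
  permeabilities P_leaflet = 2·P_membrane (a pure membrane being two
  identical leaflets in series, so identical parents reproduce the pure
  membrane exactly). It is symmetric and direction-blind by
  construction — which is precisely its failure mode when the
  adsorbed-state stabilities of the two leaflets differ;
* the **corrected estimator**: the average of the two pure-membrane
  maxima minus the adsorbed-state minimum of the pure membrane matching
  the entry leaflet. The adsorbed minimum is located as the deepest
  interior local minimum on the entry side, overridable by an explicit
  coordinate.

`exact_permeability_isd()` provides the exact reference: the
inhomogeneous solubility-diffusion integral P = [∫ exp(G/kT) dz]⁻¹ with
unit diffusivity, for which the serial identity holds exactly on
adjoining intervals with matching plateaus. Absolute permeabilities in
cm/s are out of scope — they would require diffusivity profiles the
barrier-based analysis does not use.

## Leaflet tensions

`pressures_from_stress()` applies P_L = −(σ_xx + σ_yy)/2 and
P_N = −σ_zz pointwise to a tabulated stress profile.
`leaflet_tensions()` integrates the differential stress P_N − P_L above
and below the midplane by trapezoid, inserting an interpolated grid
point at the midplane so the split is exact — making the total
γ₊ + γ₋ invariant to the midplane choice to 10⁻¹⁰, while the individual
leaflet tensions shift with it, as they must. Units are fixed: bar and
nm in, mN/m out (1 bar·nm = 0.1 mN/m), asserted in a unit test.

The midplane itself is taken as the density-weighted mean of the lipid
tail density; a second convention (midpoint between the two outermost
peaks, for headgroup densities) is available behind `method = "peaks"`.
Both are labelled choices — tail densities constrain the midplane but do
not define a unique estimator.

`make_stress_profile()` generates synthetic stress profiles as two
Gaussian lobes of differential stress whose amplitudes are solved from
Gaussian half-space integrals (including each lobe's leakage across the
midplane) so the implied γ± equal the requested targets exactly; the
targets are recorded as metadata. Defaults of ∓4 mN/m reflect the scale
of area-matched asymmetric bilayers; tensions of tens of mN/m
(number-asymmetric membranes) work identically.

## Compositions

`membrane_asymmetry()` reports 100·|N_up − N_low|/(N_up + N_low) — the
only convention under which a 144/106 bilayer has 15% number asymmetry —
both unrounded and rounded. `peptide_net_charge()` counts +1 per
Lys/Arg, −1 per Asp/Glu, +1 for a charged N-terminus, −1 for a free
C-terminus; histidine is treated as neutral (the sequences this
analysis targets contain none, and the choice is documented rather than
hidden).

## Problem sizes and determinism

The validation runs use ~100 windows with 2·10⁴ Metropolis steps each
(the leading 5% discarded as equilibration), 0.02 nm bins, and
convergence to 10⁻⁶ kJ/mol — enough for sub-kJ/mol RMS recovery of a
150 kJ/mol barrier in a few seconds on one core, while keeping the full
test suite under a minute. Every stochastic operation takes an explicit
seed and leaves the global RNG state untouched; identical seeds give
bit-identical outputs, including the end-to-end `demo` pipeline of the
command-line wrapper.

## Known limitations

* One-dimensional analysis only: no 2D WHAM, no replica exchange, and
  no orthogonal-degree-of-freedom diagnostics.
* The bootstrap error is a stand-in for unspecified published error
  bars; it quantifies sampling noise under the generator's assumptions,
  not convergence of real MD.
* MBAR-style estimators are not implemented; the likelihood
  formulation appears only as an independent cross-check in the tests.
* Relative permeabilities assume a flat diffusivity profile; no
  kinetic rate theory beyond P ∝ exp(−ΔΔG_B/kT).
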