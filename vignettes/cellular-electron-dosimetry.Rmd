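---
title: "Cellular electron dosimetry for beta and Auger emitters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular electron dosimetry for beta and Auger emitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Targeted radionuclide therapy delivers an electron-emitting radionuclide
to tumour cells through a targeting vector.  For macroscopic tumours a
medium-energy beta emitter such as ^177^Lu works well, because the
millimetre-scale electron range produces a smooth cross-fire dose.  For
*single tumour cells and micrometastases* most of that energy escapes:
the question this package addresses is how much dose actually reaches a
cell nucleus, and how much better ^161^Tb — a beta emitter with nearly
the same beta spectrum but a much richer complement of conversion
electrons (CE) and Auger electrons (AE) — performs at that scale.

Both nuclides are compared under a fixed *energy-release normalization*:
1 MeV of electron energy released per µm³ of labelled volume, i.e.
1436.8 MeV for the default 14 µm cell.  This removes the trivial
difference in energy per decay (147.9 keV for ^177^Lu vs 202.5 keV for
^161^Tb) and isolates *where* each nuclide deposits its energy.
Photons are not transported: their contribution to these microscopic
targets is negligible compared to electrons and they would only add a
small, nearly uniform background.

## Phantoms

* **Single cell** (`cellModel()`): concentric spheres of unit-density
  water — a 14 µm cell, a 10 nm membrane lining the inside of the cell
  surface, and a centred 10 µm nucleus.  The nucleus occupies ~36 % of
  the cell volume, typical of tumour cells.
* **Cluster** (`makeCluster()`): 19 identical cells on a simple cubic
  lattice — one central cell, 6 first-neighbourhood cells in direct
  contact (centres one pitch away) and 12 second-neighbourhood cells at
  pitch·√2.  The default pitch is one cell diameter (14 µm), i.e. the
  cells touch; the maximum enclosing diameter is ≈ 53 µm.  The exact
  packing of a real micrometastasis is unknown; pitch is configurable.
* **Sphere** (`spherePhantom()`): a homogeneous water sphere of
  arbitrary radius, labelled uniformly — the classical geometry for
  absorbed-fraction arguments.

Source distributions are uniform on the cell surface, uniform in the
cytoplasm, uniform in the nucleus, or uniform in the whole cell.  The
*cell surface* source is placed on the outer 7 µm sphere rather than
spread through the 10 nm membrane (`surfaceMode` option): the membrane
is three orders of magnitude thinner than the transport resolution, so
the difference is immaterial.  The membrane counts toward the cell
volume but is never a source or a target.  The target is always the
nucleus, the critical structure for radiation-induced cell death.
Region boundaries use half-open shells `[inner, outer)`; a point exactly
on the nucleus surface belongs to the cytoplasm.

## Emission models

The per-decay electron emission model of each nuclide
(`radionuclide()`) has two parts:

* **Beta branches.**  Continuous spectra of the standard allowed form
  `p·W·(E₀−E)²·F(Z,E)` with a Fermi Coulomb correction, sampled by
  inverse CDF.  The dominant transitions of both nuclides are in fact
  first-forbidden, which softens the true spectra relative to the
  allowed shape.  Rather than model forbidden shape factors, the
  package keeps the *physical endpoints* (e.g. 497.8 keV for ^177^Lu,
  593.7 keV for ^161^Tb, which set the maximum range) and uses
  *effective branch fractions* fitted once so the spectral mean matches
  the evaluated mean beta energy (133.3 / 154.3 keV).  For ^161^Tb an
  additional soft effective branch (250 keV endpoint) absorbs the
  forbidden-shape difference.  A validity method rejects any model whose
  mean departs by more than 2 %.
* **Discrete CE/AE lines.**  Full evaluated line lists contain hundreds
  of entries; the package embeds a compact *effective line set* per
  nuclide (7–9 CE, 7 AE lines) whose energies are physically plausible
  conversion/Auger energies of the daughter atom and whose yields were
  solved — once, from the summary data alone — to reproduce exactly the
  CE and AE energy per decay (13.52 / 1.13 keV for ^177^Lu, 39.28 /
  8.94 keV for ^161^Tb) and their yield-weighted average energies (87 /
  1 keV and 28 / 0.8 keV), with all energies inside the evaluated
  ranges.  Yields above one (AE cascades) are sampled as
  `floor(yield)` plus a Bernoulli remainder, preserving the expectation
  without modelling cascade correlations.  A user-supplied full line or
  branch table (delimited text) supersedes the effective set and is held
  to the same calibration invariants.

Half-life is metadata only: the normalization is energy-based, so no
decay-time integration is performed.

This emission module is also the package's synthetic-data generator.
What it emulates faithfully: the per-decay energy budget, its split
into beta/CE/AE components, the spectral mean and endpoints, and the
stochastic per-decay multiplicity of cascade electrons.  What it does
not emulate: the fine line structure of the real spectra,
cascade-internal correlations, and forbidden spectral shapes.  Passing
tests therefore demonstrate correct *energy-budget* dosimetry, not
line-by-line spectroscopy; quantities dominated by where a few keV of
energy sits within a line group (e.g. sub-µm DNA-scale dosimetry) are
outside what this generator can support.

## Electron transport

The reference engine for this problem class is event-by-event
track-structure Monte Carlo with liquid-water cross sections.
Re-implementing such cross sections is out of scope here; the package
instead uses a **straight-line continuous-slowing-down (CSDA) dose
point kernel**:

* A collision stopping-power table for liquid water
  (`stoppingPowerWater()`, shipped as plain text, 10–1000 keV standard
  reference values, log–log interpolated).  Below 10 keV the table is
  extended by a smooth power law `S ∝ E^(−0.75)` anchored at 10 keV;
  this reproduces the reference CSDA range at 10 keV (2.5 µm) and the
  extension region only concerns electrons whose entire range is below
  ~2 µm, which deposit essentially locally at the scales resolved here.
* `buildKernel()` integrates `dE/ds = −S(E)` to obtain the residual
  energy after path length `r`, giving the cumulative radial deposition
  profile `F(r, E) = (E − E_res(r))/E` for an isotropic point source:
  `F(0)=0`, monotone, `F(r≥range)=1`.  Delta-ray energy is deposited
  locally along the primary path (secondary ranges are sub-µm at these
  energies) and angular scattering is neglected.
* Scoring into a spherical target is analytic: the fraction of the
  shell of radius `r` around a source at distance `ρ` that lies inside
  a target sphere has the closed form implemented in
  `shellOverlapFraction()`, and the expected deposit is the quadrature
  `Σ f_shell(ρ, r)·ΔF(r, E)` (`energyToTarget()`).  The drivers
  precompute this quadrature on a (ρ, log E) grid and score each
  sampled electron by bilinear interpolation of the *deposited
  fraction* — interpolating fractions rather than absolute deposits
  keeps limiting cases (full containment) exact.

A stepped **track mode** retains per-track scoring for
cross-validation: straight tracks advanced by a fixed fraction of the
residual range (default 5 %), each step's energy loss deposited into
the region containing the step midpoint, the residual deposited locally
once the energy falls below the 7.4 eV electronic-excitation cutoff of
water (energies below the stopping-power table floor of 50 eV behave
identically — both are far below any resolved length scale).  Energy is
conserved exactly by construction.  Inside the drivers the step is
additionally capped at one eighth of the target radius, because
midpoint scoring cannot otherwise resolve a 5 µm nucleus with the
11 µm steps a 133 keV electron would take.

### Declared accuracy consequences

Straight-line transport has no lateral scattering: real electron tracks
detour, which increases the energy deposited per unit *radial* distance
near the source and shortens the effective radial penetration.  Both
effects matter most for sources separated from the target by a few µm.
In the acceptance comparisons this shows up as cross-gap doses
(cell-surface sources, cluster cross-dose) running about 5–15 % low for
the beta-dominated ^177^Lu and slightly high for the CE-dominated
^161^Tb; self-dose-dominated configurations agree to a few percent.
The ^161^Tb/^177^Lu dose *ratio* for the cell-surface single-cell
configuration inherits both opposite-sign biases and is the least
accurate quantity the package reports (about +20 % against the
reference value); all other ratios agree within ~11 %.  Users needing
few-percent accuracy for surface-source geometries should substitute a
scattering-aware kernel via the stopping-power/kernel extension points.

## Monte Carlo design

* **Expected-value scoring.**  Each sampled decay contributes the
  direction-averaged expected deposit of its electrons, not a binary
  per-track outcome.  This is a large variance reduction: only the
  position and emission-energy sampling fluctuate.
* **Normalization.**  `normalizationFactor()` converts the energy
  density to decays: `N = energyDensity · V_cell / Ē` with `Ē` the
  analytic mean electron energy per decay; doses are
  `mevToGy(E, V) = E·1.602177×10⁻¹³ J/MeV ÷ (V·10⁻¹⁵ kg/µm³)`.  The
  local-deposition bound for intranuclear sources (all 1436.8 MeV in
  the 523.6 µm³ nucleus) is 439.6 Gy; the infinite-medium equilibrium
  dose is 160.22 Gy per 1 MeV/µm³.
* **Cluster symmetry.**  All 19 cells are identically labelled; by
  symmetry the dose to a cell depends only on its neighbourhood.  The
  driver groups source cells into *distance classes* relative to each
  representative target (central, one n1 cell, one n2 cell), samples
  each class once and weights by multiplicity.  A
  `collapseSymmetry = FALSE` mode scores all 19 targets independently
  and is used by the test suite to verify the symmetry empirically
  (pooled-SEM 3–4 σ agreement).
* **Sphere runs** stratify the source radius (refined shells around the
  target, geometric shells outwards) because a uniform-in-volume sample
  of a 2 mm phantom almost never lands near a 50 µm central target;
  stratification makes the equilibrium-dose check converge with a few
  10⁴ samples.
* **Uncertainty.**  Runs are split into batches (default 20); the
  reported SEM is the standard error over batch means.  The reference
  work reports no uncertainties, so this is an addition.
* **Determinism.**  One RNG stream per run, seeded from the
  configuration; identical configurations reproduce bit-identical
  reports.  Quadrature grids are deterministic; randomness enters only
  through position and emission sampling.

### Problem sizes

Defaults follow the reference protocol of 10⁶ decays per single-cell
configuration.  The cluster drivers default to the configured
`nDecays` *per source distance class*; because expected-value scoring
leaves only position/energy variance, 10⁵–2×10⁵ decays per class
already give per-mille precision, and the test suite and acceptance
script use those sizes.  Sphere runs use 10⁵ sampled positions.  On one
CPU a 10⁶-decay single-cell run takes seconds to tens of seconds and a
full cluster configuration well under a minute.

## Numerical choices

* Kernel grids: 160 log-spaced energies (0.05–700 keV, covering all
  sampled emissions) × 400 log-spaced radii (1 nm – 2.9 mm, beyond the
  range of the highest grid energy).  Grid-refinement tests hold
  deposits stable within 1 %.
* Deposit tables: linear ρ grids at ~0.02 µm (single cell), ~0.05 µm
  (cluster) resolution; bilinear interpolation in (ρ, log E).
* CSDA ranges: log-trapezoid quadrature, 2000 steps, Richardson-checked
  to < 0.5 %.
* Beta spectra: 3000-point trapezoid tables per branch (30000 points
  for the normalization of the exported pdf, accurate to ~10⁻⁸).
* Ties/boundaries: half-open region shells; the kernel's first radius
  bin is represented at half its upper edge.

## Known limitations

* No angular scattering, energy-loss straggling, or explicit delta-ray
  transport; biases as declared above.
* No photon transport (negligible for these targets, but a user
  comparing against activity-normalized data must add it).
* Effective emission models reproduce energy budgets, not line-level
  spectroscopy; DNA-scale dosimetry is out of scope.
* Water-equivalent, unit-density media only; spherical cells and nuclei
  on a simple cubic lattice; no additional neighbourhood shells beyond
  the second.
* Half-life and dose-rate effects, cell-survival modelling and
  radiobiology are out of scope.

## Reproducing the study tables

`runFullStudy()` runs the full experiment grid (both nuclides, all four
distributions, single cell + cluster) and `renderTables()` writes the
three summary tables; `doseFigure()` draws the grouped-bar comparison.
The command-line wrapper does the same end to end:

```sh
celldosim --experiment full_study --decays 200000 --seed 1 --out results/
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
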