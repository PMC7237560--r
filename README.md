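# celldosim

Monte Carlo cellular dosimetry for electron-emitting radionuclides used
in targeted radionuclide therapy (TRT).  The package answers a concrete
therapy-design question: **how much absorbed dose reaches the nucleus of
a single tumour cell, or of cells in a micrometastasis-sized cluster,
from ¹⁶¹Tb compared to ¹⁷⁷Lu**, for different subcellular locations of
the radionuclide (cell surface, cytoplasm, nucleus, whole cell).  It is
aimed at medical-physics and radiopharmaceutical researchers evaluating
electron emitters for treating minimal residual disease, where most of a
conventional β⁻ emitter's energy escapes the target.

## Model

* **Phantoms.** A cell is three concentric spheres of unit-density
  water: cell radius 7 µm, a 10 nm membrane lining the cell surface, and
  a 5 µm nucleus (the target).  A micrometastasis is 19 such cells on a
  simple cubic lattice: a central cell, 6 first-neighbourhood and 12
  second-neighbourhood cells.  Water spheres of arbitrary radius support
  classical absorbed-fraction comparisons.
* **Emissions.** Per decay, one β⁻ electron (allowed-shape spectrum
  *p W (E₀−E)² F(Z,E)*, branch structure calibrated so the spectral mean
  matches evaluated nuclear data: 133.3 keV for ¹⁷⁷Lu, 154.3 keV for
  ¹⁶¹Tb) plus discrete conversion-electron and Auger-electron lines with
  per-decay yields calibrated to the evaluated energy budgets
  (CE + AE: 14.7 keV/decay for ¹⁷⁷Lu vs 48.2 keV/decay for ¹⁶¹Tb — the
  source of ¹⁶¹Tb's short-range advantage).
* **Transport.** Straight-line continuous-slowing-down (CSDA) dose point
  kernels built from a collision stopping-power table for liquid water:
  *F(r, E) = (E − E_res(r))/E* gives the cumulative energy fraction
  deposited within radius *r*; the expected deposit in a spherical
  target is the analytic quadrature ∑ f_shell(ρ, r) ΔF(r, E).  A stepped
  track mode cross-validates the kernel.  Photons are neglected.
* **Normalization.** Doses are normalized to 1 MeV of released electron
  energy per µm³ (1436.8 MeV per cell), so the two nuclides are compared
  per unit of released energy, and are decomposed into self-dose (a
  cell's own decays) and cross-dose (all other cells), with batch SEMs.

The absorbed dose is *D = N · ⟨e⟩ / m*, with *N* the decays realizing
the normalization, ⟨e⟩ the expected per-decay energy deposit in the
nucleus, and *m* the nucleus mass; the limiting anchors
*D_eq = 160.22 Gy* (infinite medium, 1 MeV/µm³) and *D_local = 439.6 Gy*
(all cell energy absorbed in the nucleus) follow from the unit
conversion alone.

## Worked example

```r
library(celldosim)

nuc <- radionuclide("tb161")
nuc
#> RadionuclideData: tb161
#>   half-life: 6.906 days (metadata only)
#>   beta branches: 3 (mean 154.3 keV, ref 154.3 keV)
#>   CE lines: 9 (39.28 keV/decay, ref 39.28)
#>   AE lines: 7 (8.94 keV/decay, ref 8.94)
#>   total electron energy per decay: 202.5 keV (ref 202.5)

# dose to the nucleus of one cell labelled in its nucleus
cfg <- runConfig(nuc, distribution = "nucleus", nDecays = 2e5, seed = 1)
runSingleCell(cfg)
#> DoseReport: single_cell, tb161, nucleus
#>   target dose_Gy self_Gy cross_Gy self_pct sem_Gy
#>  nucleus   38.72   38.72        0      100 0.0247

# the same cell inside a 19-cell cluster, all cells labelled alike
runCluster(runConfig(nuc, "nucleus", nDecays = 5e4, seed = 1))
#> DoseReport: cluster, tb161, nucleus
#>   target dose_Gy self_Gy cross_Gy self_pct  sem_Gy
#>  central   45.41   38.68    6.730    85.18 0.04689
#>       n1   44.06   38.74    5.324    87.92 0.05015
#>       n2   42.25   38.73    3.511    91.69 0.06157
```

Reading the numbers: an intranuclear ¹⁶¹Tb label delivers ≈ 39 Gy to a
single cell's nucleus per 1436.8 MeV released — versus ≈ 10.5 Gy for
¹⁷⁷Lu under the same normalization (enhancement factor ≈ 3.7), because
¹⁶¹Tb's low-energy conversion and Auger electrons stop inside the
nucleus while most β energy escapes.  In the cluster, cross-fire from
the 18 neighbours adds ~3.5–6.7 Gy depending on position, and the
self-dose share grows from the central cell outwards.

The command-line wrapper runs the same experiments and regenerates the
summary tables and the grouped-bar figure:

```sh
inst/exec/celldosim --experiment full_study --decays 200000 --seed 1 --out results/
```

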