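#' @import methods
NULL

#' RadionuclideData: electron emission model of one radionuclide
#'
#' Holds the per-decay electron emission model: one or more beta branches
#' (continuous spectra) plus discrete conversion-electron (CE) and
#' Auger-electron (AE) lines with yields per decay.  Reference summary
#' quantities (mean beta energy, CE/AE energy per decay, total electron
#' energy per decay) are stored alongside and enforced by the validity
#' method, so that any embedded or user-supplied model is guaranteed to be
#' calibrated against its nuclear-data summary.
#'
#' @slot name radionuclide identifier, e.g. `"lu177"`.
#' @slot halfLifeDays physical half-life in days (metadata only; dose
#'   normalization is energy-based, so no decay-time integration is done).
#' @slot daughterZ atomic number of the daughter nuclide, used in the Fermi
#'   correction of the beta spectra.
#' @slot betaBranches `data.frame` with columns `endpoint_keV`, `fraction`,
#'   `shape` (`"allowed_fermi"` or `"effective_single"`).
#' @slot lines `data.frame` with columns `kind` (`"CE"` or `"AE"`),
#'   `energy_keV`, `yield` (electrons per decay; AE yields may exceed 1).
#' @slot meanBetaEnergyRef reference mean beta energy (keV).
#' @slot totalElectronEnergyRef reference total electron energy per decay (keV).
#' @slot ceEnergyPerDecayRef,aeEnergyPerDecayRef reference CE and AE energy
#'   per decay (keV).
#' @slot spectra per-branch list of precomputed spectra
#'   (`E`, `pdf`, `cdf`, `mean`), filled by [radionuclide()].
#'
#' @seealso [radionuclide()], [sampleEmissions()], [meanEnergyPerDecay()]
#' @export
setClass("RadionuclideData",
  slots = c(
    name = "character",
    halfLifeDays = "numeric",
    daughterZ = "numeric",
    betaBranches = "data.frame",
    lines = "data.frame",
    meanBetaEnergyRef = "numeric",
    totalElectronEnergyRef = "numeric",
    ceEnergyPerDecayRef = "numeric",
    aeEnergyPerDecayRef = "numeric",
    spectra = "list"
  )
)

setValidity("RadionuclideData", function(object) {
  msg <- character()
  br <- object@betaBranches
  ln <- object@lines
  if (nrow(br) == 0L) msg <- c(msg, "at least one beta branch is required")
  if (any(br$endpoint_keV <= 0)) msg <- c(msg, "beta endpoints must be positive")
  if (abs(sum(br$fraction) - 1) > 1e-9)
    msg <- c(msg, "beta branch fractions must sum to 1")
  if (nrow(ln) > 0L) {
    if (any(ln$energy_keV <= 0)) msg <- c(msg, "line energies must be positive")
    if (any(ln$yield <= 0)) msg <- c(msg, "line yields must be positive")
    if (!all(ln$kind %in% c("CE", "AE")))
      msg <- c(msg, "line kind must be 'CE' or 'AE'")
  }
  # calibration invariants against the reference summary data
  if (length(object@spectra) == nrow(br)) {
    meanBeta <- sum(br$fraction * vapply(object@spectra, `[[`, 0, "mean"))
    if (abs(meanBeta / object@meanBetaEnergyRef - 1) > 0.02)
      msg <- c(msg, sprintf(
        "model mean beta energy %.1f keV departs >2%% from reference %.1f keV",
        meanBeta, object@meanBetaEnergyRef))
    ce <- sum(ln$energy_keV[ln$kind == "CE"] * ln$yield[ln$kind == "CE"])
    ae <- sum(ln$energy_keV[ln$kind == "AE"] * ln$yield[ln$kind == "AE"])
    if (object@ceEnergyPerDecayRef > 0 &&
        abs(ce / object@ceEnergyPerDecayRef - 1) > 0.05)
      msg <- c(msg, "CE energy per decay departs >5% from reference")
    if (object@aeEnergyPerDecayRef > 0 &&
        abs(ae / object@aeEnergyPerDecayRef - 1) > 0.05)
      msg <- c(msg, "AE energy per decay departs >5% from reference")
    tot <- meanBeta + ce + ae
    if (abs(tot / object@totalElectronEnergyRef - 1) > 0.05)
      msg <- c(msg, "total electron energy per decay departs >5% from reference")
  }
  if (length(msg)) msg else TRUE
})

#' CellModel: nested-sphere phantom of a tumour cell
#'
#' A cell of unit-density water: an outer sphere (the cell), a thin
#' membrane shell on its inside surface, and a concentric spherical
#' nucleus.  Defaults give a 14 um cell with a 10 nm membrane and a 10 um
#' nucleus.
#'
#' @slot cellRadius outer cell radius in um.
#' @slot nucleusRadius nucleus radius in um.
#' @slot membraneThickness membrane thickness in um.
#' @slot center cell centre, 3-vector in um.
#' @slot density mass density in g/cm3 (water, 1.0).
#' @seealso [cellModel()], [regionOf()], [sampleSourcePositions()]
#' @export
setClass("CellModel",
  slots = c(
    cellRadius = "numeric",
    nucleusRadius = "numeric",
    membraneThickness = "numeric",
    center = "numeric",
    density = "numeric"
  )
)

setValidity("CellModel", function(object) {
  msg <- character()
  if (object@cellRadius <= 0) msg <- c(msg, "cellRadius must be positive")
  if (object@nucleusRadius <= 0) msg <- c(msg, "nucleusRadius must be positive")
  if (object@membraneThickness < 0) msg <- c(msg, "membraneThickness must be >= 0")
  if (object@nucleusRadius + object@membraneThickness >= object@cellRadius)
    msg <- c(msg, "nucleus plus membrane must fit inside the cell")
  if (length(object@center) != 3L) msg <- c(msg, "center must be a 3-vector")
  if (object@density <= 0) msg <- c(msg, "density must be positive")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: 19-cell simple-cubic micrometastasis phantom
#'
#' A central cell, its 6 face neighbours at one lattice pitch (first
#' neighbourhood) and its 12 edge neighbours at pitch times sqrt(2)
#' (second neighbourhood), all identical \linkS4class{CellModel} phantoms.
#'
#' @slot cells list of \linkS4class{CellModel} objects (19 at defaults).
#' @slot neighbourhood per-cell label, one of `"central"`, `"n1"`, `"n2"`.
#' @slot pitch lattice pitch in um.
#' @seealso [makeCluster()]
#' @export
setClass("ClusterModel",
  slots = c(cells = "list", neighbourhood = "character", pitch = "numeric")
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  lab <- object@neighbourhood
  if (length(object@cells) != length(lab))
    msg <- c(msg, "one neighbourhood label per cell is required")
  if (sum(lab == "central") != 1L) msg <- c(msg, "exactly one central cell required")
  if (sum(lab == "n1") != 6L) msg <- c(msg, "first neighbourhood must have 6 cells")
  if (sum(lab == "n2") != 12L) msg <- c(msg, "second neighbourhood must have 12 cells")
  ctr <- t(vapply(object@cells, function(c) c@center, numeric(3)))
  d0 <- sqrt(rowSums(ctr^2))
  p <- object@pitch
  if (any(abs(d0[lab == "n1"] - p) > 1e-9))
    msg <- c(msg, "n1 cells must sit at one pitch from the centre")
  if (any(abs(d0[lab == "n2"] - p * sqrt(2)) > 1e-9))
    msg <- c(msg, "n2 cells must sit at pitch*sqrt(2) from the centre")
  r <- object@cells[[1]]@cellRadius
  if (p < 2 * r - 1e-12) msg <- c(msg, "cells overlap: pitch < cell diameter")
  if (length(msg)) msg else TRUE
})

#' SpherePhantom: homogeneous water sphere
#'
#' @slot radius sphere radius in um.
#' @slot density mass density in g/cm3.
#' @seealso [spherePhantom()], [runSphere()]
#' @export
setClass("SpherePhantom", slots = c(radius = "numeric", density = "numeric"))

setValidity("SpherePhantom", function(object) {
  if (object@radius <= 0) "radius must be positive" else TRUE
})

#' StoppingPowerTable: collision stopping power of electrons in water
#'
#' Tabulated collision stopping power in unit-density water, log-log
#' interpolated, together with a precomputed fine-grained CSDA
#' range-energy relation used for residual-energy lookups.
#'
#' @slot energy energy grid in keV.
#' @slot S collision stopping power in keV/um at the grid energies.
#' @slot rangeEnergy,rangeValue fine grids of energy (keV) and CSDA range
#'   (um) used for fast range and inverse-range interpolation.
#' @seealso [stoppingPowerWater()], [csdaRange()], [buildKernel()]
#' @export
setClass("StoppingPowerTable",
  slots = c(energy = "numeric", S = "numeric",
            rangeEnergy = "numeric", rangeValue = "numeric")
)

setValidity("StoppingPowerTable", function(object) {
  msg <- character()
  if (length(object@energy) != length(object@S))
    msg <- c(msg, "energy and S must have equal length")
  if (any(object@S <= 0)) msg <- c(msg, "stopping power must be positive")
  if (is.unsorted(object@energy, strictly = TRUE))
    msg <- c(msg, "energy grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' TransportKernel: cumulative radial energy-deposition profiles
#'
#' For an isotropic point source of monoenergetic electrons in water,
#' `F[r, E]` is the cumulative fraction of the initial energy `E`
#' deposited within radial distance `r`, built under the straight-line
#' continuous-slowing-down approximation.
#'
#' @slot energyGrid energy grid in keV (columns of `F`).
#' @slot radiusGrid radius grid in um (rows of `F`).
#' @slot F matrix of cumulative deposited-energy fractions.
#' @slot table the \linkS4class{StoppingPowerTable} the kernel was built from.
#' @seealso [buildKernel()], [energyToTarget()]
#' @export
setClass("TransportKernel",
  slots = c(energyGrid = "numeric", radiusGrid = "numeric",
            F = "matrix", table = "StoppingPowerTable")
)

setValidity("TransportKernel", function(object) {
  msg <- character()
  Fm <- object@F
  if (nrow(Fm) != length(object@radiusGrid) || ncol(Fm) != length(object@energyGrid))
    msg <- c(msg, "F must be radius x energy")
  if (any(Fm < -1e-12) || any(Fm > 1 + 1e-12))
    msg <- c(msg, "F must lie in [0, 1]")
  if (any(apply(Fm, 2, function(x) any(diff(x) < -1e-12))))
    msg <- c(msg, "F must be non-decreasing in radius")
  if (any(abs(Fm[nrow(Fm), ] - 1) > 1e-6))
    msg <- c(msg, "F must reach 1 at the largest radius (full absorption)")
  if (length(msg)) msg else TRUE
})

#' RunConfig: parameters of one dosimetry simulation
#'
#' @slot radionuclide a \linkS4class{RadionuclideData} emission model.
#' @slot distribution source distribution, one of `"cell_surface"`,
#'   `"cytoplasm"`, `"nucleus"`, `"whole_cell"`.
#' @slot nDecays number of simulated decays per source region.
#' @slot nBatches number of statistical batches for the SEM.
#' @slot seed RNG seed.
#' @slot energyDensity released electron energy per unit volume, MeV/um3.
#' @slot cell the \linkS4class{CellModel} phantom.
#' @slot transport list with `mode` (`"kernel"` or `"track"`),
#'   `cutoff_eV` (local-absorption threshold) and `stepFraction`
#'   (track-mode step size as a fraction of the residual range).
#' @seealso [runConfig()], [runSingleCell()], [runCluster()]
#' @export
setClass("RunConfig",
  slots = c(
    radionuclide = "RadionuclideData",
    distribution = "character",
    nDecays = "numeric",
    nBatches = "numeric",
    seed = "numeric",
    energyDensity = "numeric",
    cell = "CellModel",
    transport = "list"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@distribution %in% sourceDistributions())
    msg <- c(msg, paste("distribution must be one of:",
                        paste(sourceDistributions(), collapse = ", ")))
  if (object@nDecays < object@nBatches || object@nBatches < 2)
    msg <- c(msg, "need nDecays >= nBatches >= 2")
  if (object@energyDensity < 0) msg <- c(msg, "energyDensity must be >= 0")
  if (!object@transport$mode %in% c("kernel", "track"))
    msg <- c(msg, "transport mode must be 'kernel' or 'track'")
  if (object@transport$cutoff_eV <= 0) msg <- c(msg, "cutoff must be positive")
  if (length(msg)) msg else TRUE
})

#' DoseReport: normalized absorbed doses with self/cross decomposition
#'
#' One row per target: total absorbed dose to the target nucleus (or
#' sphere), its self-dose and cross-dose components, the self-dose
#' percentage, and the batch standard error.
#'
#' @slot results `data.frame` with columns `target`, `dose_Gy`, `self_Gy`,
#'   `cross_Gy`, `self_pct`, `sem_Gy`.
#' @slot radionuclide radionuclide name.
#' @slot distribution source distribution.
#' @slot geometry `"single_cell"`, `"cluster"` or `"sphere"`.
#' @slot config echo of the run parameters.
#' @seealso [runSingleCell()], [runCluster()], [doseGy()]
#' @export
setClass("DoseReport",
  slots = c(results = "data.frame", radionuclide = "character",
            distribution = "character", geometry = "character",
            config = "list")
)

setValidity("DoseReport", function(object) {
  msg <- character()
  res <- object@results
  need <- c("target", "dose_Gy", "self_Gy", "cross_Gy", "self_pct", "sem_Gy")
  if (!all(need %in% names(res)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(res$dose_Gy < 0)) msg <- c(msg, "doses must be non-negative")
    bad <- abs(res$self_Gy + res$cross_Gy - res$dose_Gy) >
      1e-9 * pmax(res$dose_Gy, 1e-300)
    if (any(bad)) msg <- c(msg, "self + cross must equal total dose")
    if (any(res$self_pct < -1e-9 | res$self_pct > 100 + 1e-9))
      msg <- c(msg, "self_pct must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})
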