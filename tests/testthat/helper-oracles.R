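# Shared fixtures and independent oracles, memoized across test files.

.fixtures <- new.env(parent = emptyenv())

sharedTable <- function() {
  if (is.null(.fixtures$table)) .fixtures$table <- stoppingPowerWater()
  .fixtures$table
}

sharedKernel <- function() {
  if (is.null(.fixtures$kernel)) .fixtures$kernel <- buildKernel(sharedTable())
  .fixtures$kernel
}

# independent residual-energy oracle: fine fixed-step Euler integration of
# dE/ds = -S(E), no range-table interpolation involved
oracleResidualEnergy <- function(E, pathLength, nSteps = 20000L) {
  tab <- sharedTable()
  ds <- pathLength / nSteps
  for (i in seq_len(nSteps)) {
    E <- E - stoppingPower(tab, E) * ds
    if (E <= min(tab@energy) * 1.01) return(0)
  }
  E
}

# sampled mean energy per decay at moderate n (memoized per nuclide)
sampledMeanPerDecay <- function(name, n = 2e5, seed = 101) {
  key <- paste0("mean_", name, "_", n)
  if (is.null(.fixtures[[key]])) {
    em <- sampleEmissions(radionuclide(name), n, seed = seed)
    .fixtures[[key]] <- sum(em$energy_keV) / n
  }
  .fixtures[[key]]
}

# small single-cell runs over all distributions (memoized per nuclide)
quickSingleCell <- function(name, nDecays = 3e4, seed = 11) {
  key <- paste0("sc_", name)
  if (is.null(.fixtures[[key]])) {
    doses <- vapply(sourceDistributions(), function(d) {
      cfg <- runConfig(radionuclide(name), d, nDecays = nDecays,
                       nBatches = 5, seed = seed)
      doseGy(runSingleCell(cfg, kernel = sharedKernel()))
    }, 0)
    .fixtures[[key]] <- doses
  }
  .fixtures[[key]]
}

# small cluster run (memoized per nuclide x distribution)
quickCluster <- function(name, dist, nDecays = 2e4, seed = 12) {
  key <- paste0("cl_", name, "_", dist)
  if (is.null(.fixtures[[key]])) {
    cfg <- runConfig(radionuclide(name), dist, nDecays = nDecays,
                     nBatches = 5, seed = seed)
    .fixtures[[key]] <- runCluster(cfg, kernel = sharedKernel())
  }
  .fixtures[[key]]
}
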