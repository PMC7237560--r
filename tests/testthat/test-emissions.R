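test_that("weighted average energy follows the yield-weighted formula", {
  expect_equal(weightedAverageEnergy(c(10, 20), c(1, 1)), 15)
  expect_equal(weightedAverageEnergy(c(10, 30), c(3, 1)), 15)
  expect_equal(weightedAverageEnergy(5, 0.2), 5)
  expect_equal(
    weightedAverageEnergy(data.frame(energy_keV = c(10, 30), yield = c(3, 1))),
    15)
  expect_error(weightedAverageEnergy(numeric(0), numeric(0)), "empty")
})

test_that("beta spectrum pdf is a normalized density vanishing at the endpoint", {
  for (p in list(c(497.8, 72), c(593.7, 66))) {
    expect_equal(betaSpectrumPdf(p[1], p[1], p[2]), 0)
    expect_equal(betaSpectrumPdf(-1, p[1], p[2]), 0)
    expect_equal(betaSpectrumPdf(p[1] + 10, p[1], p[2]), 0)
    v <- stats::integrate(function(E) betaSpectrumPdf(E, p[1], p[2]),
                          0, p[1], rel.tol = 1e-10)$value
    expect_equal(v, 1, tolerance = 1e-6)
    expect_true(all(betaSpectrumPdf(seq(1, p[1] - 1, by = 7), p[1], p[2]) >= 0))
  }
})

test_that("embedded emission models reproduce their reference summary data", {
  for (nm in listRadionuclides()) {
    nuc <- radionuclide(nm)
    expect_s4_class(nuc, "RadionuclideData")
    expect_equal(meanBetaEnergy(nuc), nuc@meanBetaEnergyRef, tolerance = 0.02)
    ln <- nuc@lines
    ce <- sum(ln$energy_keV[ln$kind == "CE"] * ln$yield[ln$kind == "CE"])
    ae <- sum(ln$energy_keV[ln$kind == "AE"] * ln$yield[ln$kind == "AE"])
    expect_equal(ce, nuc@ceEnergyPerDecayRef, tolerance = 0.05)
    expect_equal(ae, nuc@aeEnergyPerDecayRef, tolerance = 0.05)
    expect_equal(meanEnergyPerDecay(nuc), nuc@totalElectronEnergyRef,
                 tolerance = 0.05)
  }
  # reference values themselves
  expect_equal(radionuclide("tb161")@meanBetaEnergyRef, 154.3)
  expect_equal(radionuclide("lu177")@totalElectronEnergyRef, 147.9)
  expect_error(radionuclide("xx99"), "unsupported")
})

test_that("sampled emission streams are calibrated, bounded and reproducible", {
  ranges <- list(
    lu177 = list(CE = c(6.2, 206.3), AE = c(0.01, 61.7), beta = 497.8),
    tb161 = list(CE = c(3.3, 98.3), AE = c(0.018, 50.9), beta = 593.7))
  for (nm in listRadionuclides()) {
    nuc <- radionuclide(nm)
    em <- sampleEmissions(nuc, 2e5, seed = 101)
    # exactly one beta per decay
    expect_equal(sum(em$kind == "beta"), 2e5)
    # per-decay mean total energy within 1% of the reference
    expect_equal(sum(em$energy_keV) / 2e5, nuc@totalElectronEnergyRef,
                 tolerance = 0.01)
    # sampled mean beta energy within 2%
    expect_equal(mean(em$energy_keV[em$kind == "beta"]),
                 nuc@meanBetaEnergyRef, tolerance = 0.02)
    # energies within the physical component ranges
    rg <- ranges[[nm]]
    for (k in c("CE", "AE")) {
      Ek <- em$energy_keV[em$kind == k]
      expect_true(all(Ek >= rg[[k]][1] - 1e-12 & Ek <= rg[[k]][2] + 1e-12))
    }
    expect_true(all(em$energy_keV[em$kind == "beta"] > 0))
    expect_true(all(em$energy_keV[em$kind == "beta"] < rg$beta))
  }
})

test_that("emission streams are seed-deterministic and seed-independent", {
  nuc <- radionuclide("tb161")
  a <- sampleEmissions(nuc, 3000, seed = 5)
  b <- sampleEmissions(nuc, 3000, seed = 5)
  c <- sampleEmissions(nuc, 3000, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$energy_keV, c$energy_keV)))
})

test_that("line yields above one produce integer counts with the right expectation", {
  nuc <- radionuclide("tb161")
  y <- nuc@lines$yield[which.max(nuc@lines$yield)]  # about 4.75
  expect_gt(y, 1)
  em <- sampleEmissions(nuc, 5e4, seed = 9)
  E0 <- nuc@lines$energy_keV[which.max(nuc@lines$yield)]
  counts <- tabulate(em$decay[em$kind == "AE" & em$energy_keV == E0],
                     nbins = 5e4)
  expect_setequal(unique(counts), c(floor(y), floor(y) + 1))
  expect_equal(mean(counts), y, tolerance = 0.01)
})

test_that("user-supplied emission tables supersede the embedded effective sets", {
  nuc <- radionuclide("lu177")
  linesFile <- tempfile(fileext = ".tsv")
  df <- nuc@lines
  names(df) <- c("kind", "energy_keV", "yield_per_decay")
  utils::write.table(df, linesFile, sep = "\t", row.names = FALSE, quote = FALSE)
  branchesFile <- tempfile(fileext = ".csv")
  utils::write.table(nuc@betaBranches, branchesFile, sep = ",",
                     row.names = FALSE, quote = FALSE)
  nuc2 <- radionuclide("lu177", linesFile = linesFile,
                       branchesFile = branchesFile)
  expect_equal(nuc2@lines$energy_keV, nuc@lines$energy_keV)
  expect_equal(nuc2@lines$yield, nuc@lines$yield)
  expect_equal(nuc2@betaBranches$endpoint_keV, nuc@betaBranches$endpoint_keV)
  # a miscalibrated table is rejected by the validity invariants
  bad <- df
  bad$yield_per_decay <- bad$yield_per_decay * 10
  utils::write.table(bad, linesFile, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(radionuclide("lu177", linesFile = linesFile), "energy per decay")
})
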