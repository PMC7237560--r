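test_that("normalization converts energy density to decays and MeV to Gy", {
  lu <- radionuclide("lu177")
  # 1 MeV/um3 in a 1436 um3 cell releases 1436 MeV
  N <- normalizationFactor(lu, 1436)
  expect_equal(N * meanEnergyPerDecay(lu) / 1000, 1436)
  expect_equal(N, 9709, tolerance = 0.005)   # 1436 MeV / 0.1479 MeV per decay
  expect_equal(normalizationFactor(lu, 1436, energyDensity = 0), 0)
  # unit conversion anchors
  expect_equal(mevToGy(1436, 1436), 160.2177, tolerance = 1e-6)
  expect_equal(mevToGy(0, 100), 0)
  expect_equal(mevToGy(1436, 523.6), 439.4, tolerance = 1e-3)
})

test_that("batch uncertainty is the SEM over batches", {
  expect_equal(batchUncertainty(c(2, 2, 2, 2)), 0)
  expect_equal(batchUncertainty(c(1, 3)), 1)
  expect_error(batchUncertainty(3), "at least 2")
  # SEM shrinks like 1/sqrt(n batches) at fixed per-batch size
  set.seed(5)
  sems <- vapply(c(8, 32, 128), function(nb)
    mean(replicate(40, batchUncertainty(stats::rnorm(nb)))), 0)
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.2)
  expect_equal(sems[2] / sems[3], 2, tolerance = 0.2)
})

test_that("enhancement factor is the Tb/Lu dose ratio", {
  expect_equal(enhancementFactor(38.6, 10.7), 38.6 / 10.7)
  expect_equal(enhancementFactor(5, 5), 1)
  expect_error(enhancementFactor(5, 0), "zero")
})

test_that("a local-deposition kernel reproduces the intranuclear dose bound", {
  cell <- cellModel()
  bound <- mevToGy(cellVolume(cell), nucleusVolume(cell))
  expect_equal(bound, 439.6, tolerance = 1e-3)
  cfg <- runConfig(radionuclide("lu177"), "nucleus", nDecays = 1e5,
                   nBatches = 5, seed = 2)
  d <- doseGy(runSingleCell(cfg, kernel = localDepositionKernel()))
  expect_equal(unname(d), bound, tolerance = 0.01)
})

test_that("single-cell doses rank by distribution and nuclide", {
  lu <- quickSingleCell("lu177")
  tb <- quickSingleCell("tb161")
  # surface < cytoplasm < whole cell < nucleus, for both nuclides
  for (d in list(lu, tb)) {
    expect_lt(d["cell_surface"], d["cytoplasm"])
    expect_lt(d["cytoplasm"], d["whole_cell"])
    expect_lt(d["whole_cell"], d["nucleus"])
  }
  # 161Tb delivers more dose than 177Lu for every distribution
  expect_true(all(tb > lu))
})

test_that("runs are bit-identical under the same seed and differ across seeds", {
  cfg <- runConfig(radionuclide("lu177"), "cytoplasm", nDecays = 5000,
                   nBatches = 4, seed = 7)
  a <- runSingleCell(cfg, kernel = sharedKernel())
  b <- runSingleCell(cfg, kernel = sharedKernel())
  expect_identical(a@results, b@results)
  cfg2 <- runConfig(radionuclide("lu177"), "cytoplasm", nDecays = 5000,
                    nBatches = 4, seed = 8)
  c <- runSingleCell(cfg2, kernel = sharedKernel())
  expect_false(identical(a@results$dose_Gy, c@results$dose_Gy))
})

test_that("cluster doses decompose into self and cross contributions", {
  rep <- quickCluster("tb161", "cell_surface")
  res <- rep@results
  expect_setequal(res$target, c("central", "n1", "n2"))
  expect_equal(res$self_Gy + res$cross_Gy, res$dose_Gy)
  # cross-dose is non-negative: cluster central total >= single-cell total
  single <- quickSingleCell("tb161")["cell_surface"]
  expect_gte(res$dose_Gy[res$target == "central"], unname(single))
  # self-dose fraction grows outwards: central < n1 < n2
  sp <- setNames(res$self_pct, res$target)
  expect_lt(sp["central"], sp["n1"])
  expect_lt(sp["n1"], sp["n2"])
})

test_that("cluster self-dose equals the single-cell dose within MC error", {
  rep <- quickCluster("lu177", "nucleus")
  cfg <- runConfig(radionuclide("lu177"), "nucleus", nDecays = 2e4,
                   nBatches = 5, seed = 33)
  single <- runSingleCell(cfg, kernel = sharedKernel())
  self <- selfDoseGy(rep)["central"]
  tol <- 3 * sqrt(semGy(single)^2 + semGy(rep)["central"]^2) + 0.01
  expect_lt(abs(self - doseGy(single)), unname(tol))
})

test_that("first-neighbourhood cells receive equal doses by symmetry", {
  cfg <- runConfig(radionuclide("tb161"), "nucleus", nDecays = 6000,
                   nBatches = 4, seed = 44)
  rep <- runCluster(cfg, collapseSymmetry = FALSE, kernel = sharedKernel())
  res <- rep@results
  for (nbh in c("n1", "n2")) {
    idx <- res$neighbourhood == nbh
    d <- res$dose_Gy[idx]
    # pooled SEM: the per-cell 4-batch SEM estimates are themselves noisy
    sem <- sqrt(mean(res$sem_Gy[idx]^2))
    expect_true(all(abs(d - mean(d)) < 4 * sem + 1e-3),
                label = paste("doses within", nbh, "agree"))
  }
})

test_that("sphere doses grow with radius toward the equilibrium dose", {
  lu <- radionuclide("lu177")
  d10 <- doseGy(runSphere(spherePhantom(10), lu, nPositions = 8000,
                          nBatches = 4, seed = 3, kernel = sharedKernel()))
  d100 <- doseGy(runSphere(spherePhantom(100), lu, nPositions = 8000,
                           nBatches = 4, seed = 3, kernel = sharedKernel()))
  expect_lt(d10, d100)
  expect_lt(d100, 160.2177)
  # central region of a phantom much larger than the electron range sees
  # the infinite-medium equilibrium dose
  deq <- doseGy(runSphere(spherePhantom(2000), lu, nPositions = 3e4,
                          nBatches = 4, seed = 3, targetRadius = 50,
                          kernel = sharedKernel()))
  expect_equal(unname(deq), 160.2177, tolerance = 0.02)
})

test_that("track-mode and kernel-mode drivers agree on the nucleus dose", {
  luK <- runConfig(radionuclide("lu177"), "nucleus", nDecays = 4000,
                   nBatches = 4, seed = 55)
  luT <- runConfig(radionuclide("lu177"), "nucleus", nDecays = 4000,
                   nBatches = 4, seed = 55, transportMode = "track")
  a <- runSingleCell(luK, kernel = sharedKernel())
  b <- runSingleCell(luT, kernel = sharedKernel())
  tol <- 3 * sqrt(semGy(a)^2 + semGy(b)^2) + 0.03 * doseGy(a)
  expect_lt(abs(doseGy(a) - doseGy(b)), unname(tol))
})
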