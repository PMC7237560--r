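test_that("CSDA range is monotone and quadrature-converged", {
  tab <- sharedTable()
  E <- c(1, 5, 10, 50, 100, 300, 600)
  R <- csdaRange(E, tab)
  expect_true(all(diff(R) > 0))
  expect_true(all(csdaRange(2 * E[E <= 500], tab) > R[E <= 500]))
  # Richardson-style self-consistency: half the quadrature steps, < 0.5%
  Rhalf <- csdaRange(E, tab, nSteps = 1000L)
  expect_equal(Rhalf, R, tolerance = 0.005)
  # sanity anchors for water (unit density)
  expect_equal(csdaRange(10, tab), 2.5, tolerance = 0.03)
  expect_equal(csdaRange(100, tab), 143, tolerance = 0.02)
  expect_error(csdaRange(5000, tab), "outside")
})

test_that("stopping power interpolates log-log and rejects out-of-range energies", {
  tab <- sharedTable()
  expect_equal(stoppingPower(tab, 100), 0.4115, tolerance = 1e-6)
  # log-log interpolation between 100 and 125 keV
  s <- stoppingPower(tab, 110)
  expect_gt(s, 0.3591)
  expect_lt(s, 0.4115)
  expect_error(stoppingPower(tab, 2000), "outside")
  expect_true(all(diff(stoppingPower(tab, seq(1, 600, by = 3))) < 0))
})

test_that("kernel profiles are cumulative, conservative and back-loaded", {
  k <- sharedKernel()
  tab <- sharedTable()
  # validity already enforces monotonicity and F(rmax) = 1; spot-check physics
  for (E in c(10, 50, 200)) {
    R <- csdaRange(E, tab)
    j <- which.min(abs(k@energyGrid - E))
    Egrid <- k@energyGrid[j]
    Rg <- csdaRange(Egrid, tab)
    Fr <- stats::approx(k@radiusGrid, k@F[, j], xout = c(Rg * 1.05, Rg / 2))$y
    # full absorption at (and beyond) the CSDA range; the last grid cell
    # straddling the range is steep, so probe just past it
    expect_equal(Fr[1], 1, tolerance = 1e-9)
    expect_gt(stats::approx(k@radiusGrid, k@F[, j], xout = Rg)$y, 0.9)
    # deposition is back-loaded: stopping power rises as the electron
    # slows, so the first half of the path deposits less than half the
    # energy; check the half-range value against an independent
    # fixed-step Euler integration of dE/ds = -S(E)
    oracle <- 1 - oracleResidualEnergy(Egrid, Rg / 2) / Egrid
    expect_equal(Fr[2], oracle, tolerance = 0.01)
    expect_lt(Fr[2], 0.5)
  }
})

test_that("kernel is stable under radial grid refinement", {
  tab <- sharedTable()
  k1 <- sharedKernel()
  k2 <- buildKernel(tab, radiusGrid = exp(seq(log(1e-3), log(2900),
                                              length.out = 800L)))
  for (E in c(20, 150)) for (rho in c(2, 6)) {
    d1 <- energyToTarget(c(rho, 0, 0), E, c(0, 0, 0), 5, k1)
    d2 <- energyToTarget(c(rho, 0, 0), E, c(0, 0, 0), 5, k2)
    expect_equal(d1, d2, tolerance = 0.01)
  }
})

test_that("shell overlap fraction matches geometry and an isotropic MC oracle", {
  expect_equal(shellOverlapFraction(0, 3, 5), 1)
  expect_equal(shellOverlapFraction(10, 20, 5), 0)
  expect_equal(shellOverlapFraction(12, 2, 5), 0)   # rho - r >= Rtarget
  expect_equal(shellOverlapFraction(5, 5, 5), 0.25)
  # MC oracle: isotropic points on a sphere of radius r at distance rho
  set.seed(77)
  cases <- list(c(5, 5, 5), c(4, 3, 5), c(6, 4, 5), c(2, 6, 5))
  for (cs in cases) {
    rho <- cs[1]; r <- cs[2]; Rt <- cs[3]
    u <- stats::runif(1e5, -1, 1)
    phi <- stats::runif(1e5, 0, 2 * pi)
    p <- cbind(rho + r * sqrt(1 - u^2) * cos(phi),
               r * sqrt(1 - u^2) * sin(phi), r * u)
    frac <- mean(rowSums(p^2) < Rt^2)
    sig <- sqrt(frac * (1 - frac) / 1e5)
    expect_lt(abs(shellOverlapFraction(rho, r, Rt) - frac), 3 * sig + 1e-4)
  }
})

test_that("expected deposit respects containment and reach", {
  k <- sharedKernel()
  tab <- sharedTable()
  # contained: 10 keV electron (range 2.5 um) at the centre of a 5 um sphere
  expect_equal(energyToTarget(c(0, 0, 0), 10, c(0, 0, 0), 5, k), 10,
               tolerance = 1e-3)
  # out of reach: source further than radius + range
  expect_equal(energyToTarget(c(9, 0, 0), 10, c(0, 0, 0), 5, k), 0)
  # never exceeds the emitted energy
  for (E in c(5, 50, 400))
    expect_lte(energyToTarget(c(3, 0, 0), E, c(0, 0, 0), 5, k), E)
  # shell target (cytoplasm) as difference of two balls is non-negative
  d <- energyToTarget(c(6, 0, 0), 30, c(0, 0, 0), 6.99, k) -
    energyToTarget(c(6, 0, 0), 30, c(0, 0, 0), 5, k)
  expect_gt(d, 0)
})

test_that("track transport conserves energy exactly and stops locally", {
  tab <- sharedTable()
  cells <- list(cellModel())
  for (E in c(0.3, 15, 150)) {
    dep <- trackModeDeposit(c(1, 1, 1), E, c(0.3, 0.4, 0.8), cells, tab)
    expect_equal(sum(dep), E, tolerance = 1e-12)
  }
  # 5 keV from the nucleus centre: range < 1 um, all energy in the nucleus
  dep <- trackModeDeposit(c(0, 0, 0), 5, c(1, 0, 0), cells, tab)
  expect_equal(unname(dep["cell1.nucleus"]), 5, tolerance = 1e-12)
  expect_equal(sum(dep) - dep["cell1.nucleus"], c(`cell1.nucleus` = 0))
})

test_that("kernel and track modes agree on expected nucleus deposits", {
  k <- sharedKernel()
  tab <- sharedTable()
  set.seed(99)
  n <- 1500
  for (E in c(10, 30, 60)) for (rho in c(4, 6, 6.9)) {
    kd <- energyToTarget(c(rho, 0, 0), E, c(0, 0, 0), 5, k)
    td <- celldosim:::.trackScoreBatch(
      matrix(rep(c(rho, 0, 0), n), ncol = 3, byrow = TRUE),
      rep(E, n), c(0, 0, 0), 5, tab, stepFraction = 0.01)
    sem <- stats::sd(td) / sqrt(n)
    expect_lt(abs(mean(td) - kd), 3 * sem + 0.02 * E)
  }
})
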