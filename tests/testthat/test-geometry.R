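test_that("cell compartment volumes sum exactly to the cell volume", {
  cell <- cellModel()
  expect_equal(cellVolume(cell), 4 / 3 * pi * 7^3)
  expect_equal(nucleusVolume(cell), 4 / 3 * pi * 5^3)
  expect_equal(nucleusVolume(cell) + cytoplasmVolume(cell) + membraneVolume(cell),
               cellVolume(cell), tolerance = 1e-12)
  expect_error(cellModel(nucleusRadius = 7), "fit inside")
})

test_that("the cluster has the simple-cubic neighbourhood structure", {
  cl <- makeCluster(cellModel())
  expect_length(cl@cells, 19)
  expect_equal(sum(cl@neighbourhood == "central"), 1)
  expect_equal(sum(cl@neighbourhood == "n1"), 6)
  expect_equal(sum(cl@neighbourhood == "n2"), 12)
  ctr <- t(vapply(cl@cells, function(c) c@center, numeric(3)))
  d <- sqrt(rowSums(ctr^2))
  expect_equal(d[cl@neighbourhood == "n1"], rep(14, 6))
  expect_equal(d[cl@neighbourhood == "n2"], rep(14 * sqrt(2), 12))
  expect_equal(max(d) + 7, 14 * sqrt(2) + 7)  # cluster half-diameter about 27 um
  expect_error(makeCluster(cellModel(), pitch = 10), "overlap")
})

test_that("region classification uses half-open radial shells", {
  cell <- cellModel()
  expect_equal(regionOf(c(0, 0, 0), cell), "nucleus")
  expect_equal(regionOf(c(6, 0, 0), cell), "cytoplasm")
  expect_equal(regionOf(c(8, 0, 0), cell), "outside")
  # boundaries: nucleus surface -> cytoplasm, inner membrane -> membrane
  expect_equal(regionOf(c(5, 0, 0), cell), "cytoplasm")
  expect_equal(regionOf(c(7 - 0.010, 0, 0), cell), "membrane")
  expect_equal(regionOf(c(7, 0, 0), cell), "outside")
  # vectorized, off-centre cell
  cell2 <- cellModel(center = c(10, 0, 0))
  expect_equal(regionOf(rbind(c(10, 0, 0), c(16, 0, 0), c(2, 0, 0)), cell2),
               c("nucleus", "cytoplasm", "outside"))
})

test_that("source positions are contained in their regions", {
  cell <- cellModel()
  set.seed(21)
  pn <- sampleSourcePositions("nucleus", cell, 1e4)
  expect_lte(max(sqrt(rowSums(pn^2))), 5)
  ps <- sampleSourcePositions("cell_surface", cell, 1e4)
  expect_equal(sqrt(rowSums(ps^2)), rep(7, 1e4), tolerance = 1e-9)
  pc <- sampleSourcePositions("cytoplasm", cell, 1e4)
  rc <- sqrt(rowSums(pc^2))
  expect_gte(min(rc), 5)
  expect_lte(max(rc), 7 - 0.010)
  pw <- sampleSourcePositions("whole_cell", cell, 1e4)
  expect_lte(max(sqrt(rowSums(pw^2))), 7)
  # off-centre cells shift the samples
  cellOff <- cellModel(center = c(14, 0, 0))
  po <- sampleSourcePositions("nucleus", cellOff, 100)
  expect_lte(max(sqrt(rowSums(sweep(po, 2, c(14, 0, 0))^2))), 5)
})

test_that("whole-cell sampling is uniform in volume", {
  set.seed(31)
  p <- sampleSourcePositions("whole_cell", cellModel(), 1e5)
  r <- sqrt(rowSums(p^2))
  # closed-form volume ratio: P(r <= 5) = (5/7)^3
  expect_equal(mean(r <= 5), (5 / 7)^3, tolerance = 0.01)
  # chi-square on 10 equal-volume radial bins
  edges <- 7 * (0:10 / 10)^(1 / 3)
  counts <- table(cut(r, edges))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
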