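test_that("autocorrelograms are normalized, symmetric and harmonic-invariant", {
  cc <- (0:59) / 60
  xy <- expand.grid(x = cc, y = cc)
  m <- map2d(matrix(cos(2 * pi * 3 * xy$x), 60, 60), 1)
  ac <- autocorrelogram(m)
  expect_equal(ac$values[1, 1], 1)
  # cosine in, cosine of the same frequency out
  expect_equal(ac$values[, 1], cos(2 * pi * 3 * cc), tolerance = 1e-9)
  # symmetry under lag negation
  idx <- 2:60
  expect_equal(ac$values[idx, idx], ac$values[rev(idx), rev(idx)],
               tolerance = 1e-9)
  expect_error(autocorrelogram(map2d(matrix(1, 8, 8), 1)), "constant")
})

test_that("gridness separates triangular, square and random maps", {
  for (n in c(48, 60, 96)) {
    tri <- gridness(makeTriangularPattern(n, 2, 3))$gridness
    sq <- gridness(makeSquarePattern(n, 2, 3))$gridness
    expect_gt(tri, 1)
    expect_lt(sq, 0)
    expect_gt(tri, sq)
  }
  # white noise scored at the grid frequency of interest stays near 0
  set.seed(61)
  for (r in 1:5) {
    wn <- map2d(matrix(rnorm(60^2), 60, 60), 1)
    expect_lt(abs(gridness(wn, k_max = 3)$gridness), 0.3)
  }
})

test_that("grid scale estimation is exact for harmonics and scale-invariant", {
  cc <- (0:59) / 60
  xy <- expand.grid(x = cc, y = cc)
  m <- map2d(matrix(cos(2 * pi * 3 * xy$x), 60, 60), 1)
  expect_equal(gridScale(m), 3)
  m2 <- map2d(5 + 2.7 * m$values, 1)
  expect_equal(gridScale(m2), 3)
  tri <- makeTriangularPattern(96, 2, 3)
  expect_equal(gridScale(tri), 3, tolerance = 0.17)   # 1/L frequency bins
  g1 <- gridness(tri)$gridness
  g2 <- gridness(map2d(0.3 + 10 * tri$values, 2))$gridness
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("orientation is measured from lattice peaks, modulo 60 degrees", {
  angdist <- function(a, b) {
    d <- abs((a - b) %% 60)
    min(d, 60 - d)
  }
  expect_lt(angdist(gridOrientation(makeTriangularPattern(96, 2, 3)), 0), 3)
  expect_lt(angdist(gridOrientation(
    makeTriangularPattern(96, 2, 3, orientation = 15)), 15), 3)
  # invariance under a 60-degree lattice rotation
  o1 <- gridOrientation(makeTriangularPattern(96, 2, 3, orientation = 10))
  o2 <- gridOrientation(makeTriangularPattern(96, 2, 3, orientation = 70))
  expect_lt(angdist(o1, o2), 3)
})

test_that("phase estimation recovers planted lattice offsets", {
  bin <- 2 / 96
  self <- gridPhase(makeTriangularPattern(96, 2, 3))
  expect_lt(sqrt(sum(self^2)), 3 * bin)
  shifted <- gridPhase(makeTriangularPattern(96, 2, 3, phase = c(0.12, 0)))
  expect_lt(abs(shifted[1] - 0.12), 3 * bin)
  expect_lt(abs(shifted[2]), 3 * bin)
})

test_that("output rate maps respect symmetry and degenerate limits", {
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(100, sp)
  m <- outputRateMap(ens, rep(0.05, 100), r0 = 4, n_bins = 50)
  # uniform weights + lattice inputs: spatially constant output
  expect_lt(diff(range(m$values)), 1e-6 * abs(mean(m$values)))
  m0 <- outputRateMap(ens, rep(0, 100), r0 = 4, n_bins = 50)
  expect_equal(as.vector(m0$values), rep(4, 2500), tolerance = 1e-9)
  expect_error(outputRateMap(ens, rep(0.05, 99)), "length")
})

test_that("weight maps require square lattices", {
  expect_error(weightMap(rep(0.1, 10), 1), "perfect square")
  wm <- weightMap(runif(25), 1)
  expect_s3_class(wm, "map2d")
})
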