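test_that("the default configuration peaks at the published critical point", {
  cfg <- spectrumConfig(rho = 900, kernel = defaultKernel(), a = 1.1)
  cp <- criticalPoint(cfg, eta = 2e-5)
  expect_equal(cp$k_max, 3, tolerance = 0.04)
  expect_equal(cp$lambda_max, 1, tolerance = 0.05)
  expect_equal(cp$tau_str, 5e4, tolerance = 0.02)
  expect_identical(cp$regime, "grid")
  # asymptotics: lambda -> -a for large k
  expect_equal(eigenvalueSpectrum(cfg, 50), -1.1, tolerance = 1e-6)
  # linear scaling in rho * W_tot at fixed k
  k0 <- 2.5
  base <- eigenvalueSpectrum(cfg, k0) + 1.1
  cfg2 <- spectrumConfig(rho = 1800, kernel = defaultKernel(), a = 1.1,
                         w_tot = 2)
  expect_equal(eigenvalueSpectrum(cfg2, k0) + 1.1, 4 * base,
               tolerance = 1e-12)
  expect_error(eigenvalueSpectrum(cfg, 0), "positive")
})

test_that("the long time constant controls the grid scale", {
  cfg35 <- spectrumConfig(rho = 900, kernel = adaptationKernel(0.1, 0.35, 1.06),
                          a = 1.1)
  expect_equal(criticalPoint(cfg35)$k_max, 2, tolerance = 0.04)
})

test_that("regime classification is exhaustive and matches limiting cases", {
  # positive-integral kernel with broad fields: supremum at k -> 0 (place)
  cfgP <- spectrumConfig(rho = 900,
                         spec = gaussianFieldSpec(0.2, 0.4, 1),
                         kernel = adaptationKernel(0.1, 0.16, 0.5), a = 0.5)
  expect_identical(criticalPoint(cfgP)$regime, "place")
  expect_equal(criticalPoint(cfgP)$k_max, 0)
  # vanishing density: nothing grows
  cfgN <- spectrumConfig(rho = 1, kernel = defaultKernel(), a = 1.1)
  cpN <- criticalPoint(cfgN)
  expect_identical(cpN$regime, "none")
  expect_true(is.na(cpN$k_max))
  # sweep over (tau_l, mu): regimes partition the grid, trends as published
  sw <- sweepSpectrum(function(tl, mu)
    spectrumConfig(rho = 900, kernel = adaptationKernel(0.05, tl, mu),
                   a = 1.1),
    axis1 = seq(0.08, 0.5, length.out = 8),
    axis2 = c(0.9, 1.06, 1.3))
  expect_true(all(sw$regime %in% c("grid", "place", "none")))
  # at mu = 1.06, k_max decreases and lambda_max increases with tau_l
  kc <- sw$k_max[, 2]; lc <- sw$lambda_max[, 2]
  grid_rows <- sw$regime[, 2] == "grid"
  expect_true(all(diff(kc[grid_rows]) <= 1e-9))
  expect_true(all(diff(lc[grid_rows]) >= -1e-9))
  # the default kernel parameters sit inside the patterning region
  cp_star <- criticalPoint(spectrumConfig(rho = 900,
                                          kernel = defaultKernel(),
                                          a = 1.1))
  expect_identical(cp_star$regime, "grid")
})

test_that("AHP kernels give typical grid scales only for slow output kernels", {
  kmax_at <- function(tau_out) {
    max(vapply(c(0.5, 1, 2, 5, 10, 20, 50), function(mo) {
      Keq <- ahpEquivalentKernel(ahpParams(0.005, tau_out, mo))
      cp <- suppressWarnings(
        criticalPoint(spectrumConfig(rho = 900, kernel = Keq, a = 0.2)))
      if (is.na(cp$k_max)) 0 else cp$k_max
    }, numeric(1)))
  }
  expect_lt(kmax_at(0.3), 2)
  expect_gt(kmax_at(10), 2)
})

test_that("the multi-field attenuation factor matches its Monte-Carlo oracle", {
  Ms <- c(2, 3, 5, 10, 20, 30)
  phi <- phiFactor(Ms)$phi
  # closed form: monotone decreasing, with the coarse large-M limit
  expect_true(all(diff(phi) < 0))
  expect_equal(phiFactor(1000)$phi * 1000, 4 / 3, tolerance = 0.001)
  for (i in seq_along(Ms)) {
    mc <- phiMonteCarlo(Ms[i], n_draws = 20000, seed = 50 + i)
    # the estimator itself is unbiased for E[sum(A^2)/(sum A)^2]: with
    # uniform phases, E_phase[alpha^2 | A] = sum(A_m^2) exactly
    set.seed(80 + i)
    A <- matrix(runif(4e4 * Ms[i]), 4e4, Ms[i])
    exact <- rowSums(A^2) / rowSums(A)^2
    expect_lt(abs(mc$phi_hat - mean(exact)),
              4 * (mc$se + sd(exact) / 200))
    # the closed form neglects the amplitude/path-length covariance, an
    # O(1/M) relative remainder; it converges onto the MC estimate
    expect_lt(abs(mc$phi_hat - phi[i]) / phi[i], 1 / Ms[i])
  }
  expect_error(phiFactor(1), "M >= 2")
})

test_that("irregular spectra keep the critical frequency for every M", {
  cfg <- spectrumConfig(rho = 3600, spec = gaussianFieldSpec(0.0625, 0.8, 1),
                        kernel = defaultKernel(), a = 2.5)
  k <- seq(0.2, 8, by = 0.01)
  k_reg <- k[which.max(eigenvalueSpectrum(cfg, k))]
  for (M in c(2, 5, 10, 20)) {
    lam_irr <- irregularSpectrum(cfg, k, M = M)
    expect_equal(k[which.max(lam_irr)], k_reg, tolerance = 1e-9)
  }
  # Phi = 1 reproduces the regular spectrum exactly
  expect_equal(irregularSpectrum(cfg, k, phi = 1),
               eigenvalueSpectrum(cfg, k))
})

test_that("discrete lattice eigenvalues lie on the analytic spectrum", {
  # small version of the red-dots-on-curve property (N = 400, L = 1)
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(400, sp)
  model <- correlationMatrix(ens, method = "radial")
  ev <- Re(fft(matrix(model$matrix[1, ], 20, 20)))   # block-circulant eigs
  cfg <- spectrumConfig(400, sp, defaultKernel(), a = 1.1)
  for (n in 1:5) {
    lam_d <- ev[n + 1, 1] - 1.1
    lam_a <- eigenvalueSpectrum(cfg, n)
    expect_equal(lam_d, lam_a, tolerance = 0.02)
  }
})
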