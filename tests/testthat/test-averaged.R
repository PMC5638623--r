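test_that("effective rates a and b match their published values", {
  pl <- plasticityParams(2e-5, 0.05, 1, 3.56, -8.78)
  ab <- deriveAB(pl, defaultKernel(), neuronParams(10), 0.4)
  expect_equal(ab$a, 1.1, tolerance = 0.001)
  expect_equal(ab$b, 0.488, tolerance = 1e-9)
  # closed-form overlap against direct quadrature of W(-t) K(t)
  num <- integrate(function(t) stdpWindow(pl, -t) *
                     kernelValue(defaultKernel(), t), 0, 20,
                   rel.tol = 1e-12)$value
  expect_equal(ab$overlap, num, tolerance = 1e-8)
  ab0 <- deriveAB(plasticityParams(2e-5, 0.05, w_tot = 0, 3.56, -8.78),
                  defaultKernel(), neuronParams(10), 0.4)
  expect_equal(ab0$a, 0.4 * 3.56)
  expect_equal(ab0$b, 0.4 * -8.78)
})

test_that("the radial correlation is a Mexican hat consistent with its spectrum", {
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  K <- defaultKernel()
  u <- seq(0, 0.6, by = 0.01)
  C <- correlationRadial(u, sp, K)
  expect_gt(C[1], 0)                               # attraction at short range
  expect_lt(min(C), 0)                             # repulsion domain
  expect_equal(correlationRadial(u, sp, K, w_tot = 0), rep(0, length(u)))
  # radial Fourier transform of C(u) recovers Chat(k) = Wtot 4pi^2/L^2 G^2 Ksp
  k <- 1:6
  chat_oracle <- radialFourierOracle(
    function(uu) correlationRadial(uu, sp, K), k, u_max = 2)
  chat_closed <- 1 * 4 * pi^2 / 1 *
    (1 * 0.4 / (2 * pi) * exp(-(2 * pi * k)^2 * 0.0625^2 / 2))^2 *
    spatialKernelHankel(K, 0.25, k)
  expect_lt(max(abs(chat_oracle - chat_closed)) / max(abs(chat_closed)),
            1e-3)
})

test_that("correlogram, Fourier and closed-form constructions agree", {
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(25, sp)
  Cr <- correlationMatrix(ens, method = "radial")$matrix
  Cc <- correlationMatrix(ens, method = "correlogram", n_bins = 96)$matrix
  Cf <- correlationMatrix(ens, method = "fourier")$matrix
  scale <- max(abs(Cr))
  expect_lt(max(abs(Cc - Cr)) / scale, 0.01)
  expect_lt(max(abs(Cf - Cr)) / scale, 0.01)
  expect_equal(Cc, t(Cc), tolerance = 1e-10)
  # irregular ensembles: the two general routes agree with each other
  irr <- makeIrregularEnsemble(6, 3, sp, seed = 41)
  Ci_c <- correlationMatrix(irr, method = "correlogram", n_bins = 96)$matrix
  Ci_f <- correlationMatrix(irr, method = "fourier")$matrix
  expect_lt(max(abs(Ci_c - Ci_f)) / max(abs(Ci_f)), 0.01)
  expect_equal(Ci_f, t(Ci_f), tolerance = 1e-10)
})

test_that("normalization quantities follow the mean-weight law", {
  C0 <- matrix(0, 10, 10)
  nq <- normalizationQuantities(C0, a = 2, b = 1, eta = 1e-4)
  expect_equal(nq$w_av_inf, 0.5)
  expect_equal(nq$tau_av, 1 / (1e-4 * 2))
  nq2 <- normalizationQuantities(C0, a = 2, b = 2, eta = 1e-4)
  expect_equal(nq2$w_av_inf, 1)               # doubling b doubles w_av_inf
  expect_equal(nq2$tau_av, nq$tau_av)         # tau_av unchanged
  expect_error(normalizationQuantities(matrix(1, 4, 4), a = 1, b = 1,
                                       eta = 1e-4), "unstable")
})

test_that("Euler integration reproduces the scalar linear ODE", {
  N <- 16
  ens <- makeRegularEnsemble(N)
  model <- structure(list(matrix = matrix(0, N, N), ensemble = ens),
                     class = "correlation_model")
  a <- 1.1; b <- 0.49; eta <- 2e-5
  sol <- integrateAveraged(model, a, b, eta, rep(0.2, N), t_end = 2e5,
                           dt_euler = 50, operator = "matrix",
                           checkpoints = c(5e4, 2e5))
  w_pred <- function(t) b / a + (0.2 - b / a) * exp(-eta * a * t)
  expect_equal(mean(sol$w_hist[1, ]), w_pred(5e4), tolerance = 1e-3)
  expect_equal(mean(sol$w_hist[2, ]), w_pred(2e5), tolerance = 1e-3)
})

test_that("mean-weight dynamics obeys the averaged law along trajectories", {
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(100, sp)
  model <- correlationMatrix(ens, method = "radial")
  a <- 1.1; b <- 0.49; eta <- 2e-5
  set.seed(42)
  w0 <- runif(100, 0, 0.1)
  cps <- seq(1e3, 2e4, by = 1e3)
  sol <- integrateAveraged(model, a, b, eta, w0, t_end = 2e4,
                           dt_euler = 50, checkpoints = cps, clamp = FALSE,
                           operator = "matrix")
  wav <- rowMeans(sol$w_hist)
  ncav <- 100 * mean(model$matrix)
  # d w_av / dt = eta ((N C_av - a) w_av + b), checked by finite differences
  dn <- diff(wav) / 1e3
  mid <- (wav[-1] + wav[-length(wav)]) / 2
  pred <- eta * ((ncav - a) * mid + b)
  expect_equal(dn, pred, tolerance = 0.01)
})

test_that("unclamped Fourier modes grow at the dispersion-relation rate", {
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(900, sp)
  model <- correlationMatrix(ens, method = "radial")
  cfg <- spectrumConfig(900, sp, defaultKernel(), a = 1.1)
  eta <- 2e-5
  set.seed(43)
  w0 <- pmax(rnorm(900, 5e-3, 1e-3), 0)
  cps <- c(1e4, 3e4)
  sol <- integrateAveraged(model, 1.1, 0.49, eta, w0, t_end = 3e4,
                           dt_euler = 25, checkpoints = cps, clamp = FALSE,
                           operator = "fft")
  modeAmp <- function(w, n1, n2) {
    W <- fft(matrix(w, 30, 30))
    Mod(W[n1 + 1, n2 + 1])
  }
  for (nn in list(c(3, 0), c(0, 3), c(2, 2))) {
    k <- sqrt(sum(nn^2))
    lam <- eigenvalueSpectrum(cfg, k)
    a0 <- modeAmp(w0, nn[1], nn[2])
    a1 <- modeAmp(sol$w_hist[1, ], nn[1], nn[2])
    a2 <- modeAmp(sol$w_hist[2, ], nn[1], nn[2])
    slope <- log(a2 / a1) / (eta * (cps[2] - cps[1]))
    expect_equal(slope, lam, tolerance = 0.02)
    expect_gt(a1, 0)
    expect_gt(a0, 0)
  }
})

test_that("divergence is caught with a diagnostic", {
  N <- 9
  ens <- makeRegularEnsemble(N)
  model <- structure(list(matrix = diag(N) * 50, ensemble = ens),
                     class = "correlation_model")
  expect_error(integrateAveraged(model, a = 0.1, b = 10, eta = 0.5,
                                 w_init = rep(1, N), t_end = 5e3,
                                 dt_euler = 50, operator = "matrix"),
               "diverged")
})
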