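test_that("STDP window is the normalized symmetric exponential", {
  pl <- plasticityParams(tau_w = 0.05, w_tot = 1)
  expect_equal(stdpWindow(pl, 0), 10)                 # W_tot / (2 tau_W)
  dts <- seq(-0.3, 0.3, length.out = 101)
  expect_equal(stdpWindow(pl, dts), stdpWindow(pl, -dts))
  expect_equal(stdpWindow(pl, 0.05) / stdpWindow(pl, 0), exp(-1))
  intg <- integrate(function(s) stdpWindow(pl, s), -Inf, Inf)
  expect_equal(intg$value, 1, tolerance = 1e-6)
})

test_that("frozen plasticity leaves weights untouched", {
  ens <- makeRegularEnsemble(25)
  tr <- simulateWalk(5, seed = 21)
  w0 <- runif(25, 0, 0.1)
  sim <- simulateSpiking(ens, tr, w_init = w0, freeze = TRUE, seed = 22)
  expect_identical(sim$w_hist[1, ], w0)
})

test_that("with silent synapses the output is homogeneous Poisson at r0", {
  ens <- makeRegularEnsemble(9)
  tr <- simulateWalk(100, seed = 23)
  sim <- simulateSpiking(ens, tr, neuron = neuronParams(r0 = 10),
                         w_init = rep(0, 9), freeze = TRUE, seed = 24)
  rate <- sim$n_out_spikes / sim$duration
  expect_equal(rate, 10, tolerance = 4 * sqrt(10 * 100) / (10 * 100))
})

test_that("frozen-weight mean output rate matches the ergodic expectation", {
  # E[r_out] = r0 + (1 - mu) * sum_i w_i * r_av under uniform occupancy
  ens <- makeRegularEnsemble(100)
  tr <- simulateWalk(300, seed = 25)
  w <- rep(0.3, 100)
  sim <- simulateSpiking(ens, tr, neuron = neuronParams(r0 = 10),
                         w_init = w, freeze = TRUE, seed = 26)
  expected <- 10 + (1 - 1.06) * sum(w) * 0.4
  rate <- sim$n_out_spikes / sim$duration
  expect_equal(rate, expected, tolerance = 5 * sqrt(expected / 300) / expected)
})

test_that("weights stay non-negative and runs are seed-reproducible", {
  ens <- makeRegularEnsemble(36)
  tr <- simulateWalk(20, seed = 27)
  pl <- plasticityParams(eta = 5e-3)        # aggressive updates
  a <- simulateSpiking(ens, tr, plasticity = pl, seed = 28,
                       checkpoints = c(5, 10, 20))
  expect_true(all(a$w_hist >= 0))
  b <- simulateSpiking(ens, tr, plasticity = pl, seed = 28,
                       checkpoints = c(5, 10, 20))
  expect_identical(a$w_hist, b$w_hist)
})

test_that("with weak correlations the mean weight relaxes toward b/a", {
  # small sparse ensemble: N*C_av << a, so w_av follows the scalar ODE
  # dw/dt = eta (b - a w)
  set.seed(29)
  N <- 25
  ens <- makeRegularEnsemble(N)
  dur <- 400
  tr <- simulateWalk(dur, seed = 30)
  pl <- plasticityParams(eta = 2e-3)
  ab <- deriveAB(pl, defaultKernel(), neuronParams(10), 0.4)
  w0 <- rep(0.3, N)
  sim <- simulateSpiking(ens, tr, plasticity = pl, w_init = w0,
                         checkpoints = c(dur / 2, dur), seed = 31)
  w_pred <- function(t) ab$b / ab$a + (0.3 - ab$b / ab$a) *
    exp(-pl$eta * ab$a * t)
  expect_equal(mean(sim$w_hist[1, ]), w_pred(dur / 2), tolerance = 0.08)
  expect_equal(mean(sim$w_hist[2, ]), w_pred(dur), tolerance = 0.08)
})

test_that("expected weight drift matches the averaged dynamics", {
  # the central averaging claim: E[dw/dt] from the spiking model equals
  # eta (C w - a w + b) at a frozen weight state, with C from the closed
  # form. The prediction chain itself carries small systematic
  # approximations (learning-window smoothing of order tau_W v / sigma,
  # smooth-trajectory circle approximation), so the check allows a 10%
  # systematic margin on top of the Monte-Carlo error.
  N <- 100
  sp <- gaussianFieldSpec(0.0625, 0.4, 1)
  ens <- makeRegularEnsemble(N, sp)
  kern <- defaultKernel()
  pl <- plasticityParams(eta = 5e-5)
  ab <- deriveAB(pl, kern, neuronParams(10), 0.4)
  C <- correlationMatrix(ens, kern, method = "radial")$matrix
  run_level <- function(w0val, reps = 10, horizon = 150) {
    w0 <- rep(w0val, N)
    pred <- mean(pl$eta * (as.vector(C %*% w0) - ab$a * w0 + ab$b))
    d <- vapply(seq_len(reps), function(r) {
      tr <- simulateWalk(horizon, seed = round(1e4 * w0val) + r)
      sim <- simulateSpiking(ens, tr, kern, neuronParams(10), pl,
                             w_init = w0,
                             seed = 5000 + round(1e4 * w0val) + r)
      mean((sim$w_hist[1, ] - w0) / horizon)
    }, numeric(1))
    list(pred = pred, meas = mean(d), se = sd(d) / sqrt(reps))
  }
  lo <- run_level(0.1); hi <- run_level(0.5)
  for (lev in list(lo, hi))
    expect_lt(abs(lev$meas - lev$pred), 4 * lev$se + 0.1 * abs(lev$pred))
  # slope between the two weight levels probes the decay rate a
  slope <- (hi$meas - lo$meas) / (hi$pred - lo$pred)
  expect_equal(slope, 1, tolerance = 0.15)
})
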