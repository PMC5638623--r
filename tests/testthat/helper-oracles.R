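# Shared fixtures and independent numerical oracles.

defaultKernel <- function() adaptationKernel(0.1, 0.16, 1.06)

# brute-force J0 quadrature of the spatial-kernel Hankel transform,
# independent of the closed form under test
hankelQuadOracle <- function(kernel, v, k, t_max = 8, n = 2000) {
  g <- pracma::gaussLegendre(n, 0, t_max)
  vapply(k, function(kk)
    sum(g$w * kernelValue(kernel, g$x) * besselJ(2 * pi * kk * v * g$x, 0)),
    numeric(1))
}

# numeric radial Fourier transform of a radial function (2D, cycles/m)
radialFourierOracle <- function(f, k, u_max, n = 4000) {
  g <- pracma::gaussLegendre(n, 0, u_max)
  vapply(k, function(kk)
    2 * pi * sum(g$w * g$x * f(g$x) * besselJ(2 * pi * kk * g$x, 0)),
    numeric(1))
}

# grid-quadrature spatial mean of one input's tuning curve
spatialMeanOracle <- function(ensemble, neuron, n_bins = 64) {
  mean(rateMap(ensemble, neuron, n_bins)$values)
}
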