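#' Gaussian receptive-field specification
#'
#' A single circular Gaussian firing field on the periodic arena,
#' \deqn{G(r) = \frac{L^2 r_{av}}{2\pi\sigma^2} e^{-r^2 / 2\sigma^2},}
#' normalized so that its spatial mean over the arena equals the average
#' rate \code{r_av}.
#'
#' @param sigma field width (m)
#' @param r_av spatial-average firing rate (1/s)
#' @param L arena side length (m)
#' @export
gaussianFieldSpec <- function(sigma = 0.0625, r_av = 0.4, L = 1) {
  if (!(sigma > 0 && r_av > 0 && L > 0)) stop("sigma, r_av, L must be positive")
  structure(list(sigma = sigma, r_av = r_av, L = L),
            class = "gaussian_field_spec")
}

# periodic Gaussian bump: un-normalized exp term summed over the 3x3
# nearest images (exact to <1e-6 of peak for sigma <= L/4)
periodicGaussian <- function(dx, dy, sigma, L) {
  dx <- torusDelta(dx, L); dy <- torusDelta(dy, L)
  acc <- 0
  for (sx in c(-L, 0, L))
    for (sy in c(-L, 0, L))
      acc <- acc + exp(-((dx + sx)^2 + (dy + sy)^2) / (2 * sigma^2))
  acc
}

#' Spatially-regular input ensemble
#'
#' \code{N} input neurons, each with a single Gaussian field; the field
#' centers tile the arena on an even \eqn{\sqrt N \times \sqrt N} lattice
#' (density \eqn{\rho = N/L^2}).
#'
#' @param N number of inputs; must be a perfect square
#' @param spec a [gaussianFieldSpec()]
#' @return an \code{input_ensemble} of kind \code{"regular"}
#' @export
makeRegularEnsemble <- function(N, spec = gaussianFieldSpec()) {
  s <- round(sqrt(N))
  if (s * s != N) stop("N must be a perfect square")
  cc <- (seq_len(s) - 1) / s * spec$L
  centers <- as.matrix(expand.grid(x = cc, y = cc))
  structure(list(kind = "regular", N = N, M = 1L,
                 centers = centers,
                 amplitudes = matrix(1, N, 1),
                 beta = rep(1, N),
                 spec = spec, seed = NULL),
            class = "input_ensemble")
}

#' Spatially-irregular input ensemble
#'
#' Each of the \code{N} inputs superimposes \code{M} Gaussian fields with
#' centers uniform on the torus and amplitudes \eqn{A_{ij} \sim U(0,1)}
#' (exact-zero draws rejected); the normalizers \eqn{\beta_i = \sum_j A_{ij}}
#' fix every neuron's spatial-mean rate at \code{r_av} regardless of
#' \code{M}.
#'
#' @param N number of inputs
#' @param M fields per neuron, \code{M >= 1}
#' @param spec a [gaussianFieldSpec()]
#' @param seed optional integer seed (stored; reproduces the ensemble)
#' @export
makeIrregularEnsemble <- function(N, M, spec = gaussianFieldSpec(),
                                  seed = NULL) {
  if (M < 1) stop("M must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(runif(N * M * 2, 0, spec$L), N * M, 2) # row (i-1)*M+m
  amp <- matrix(runif(N * M), N, M)
  while (any(amp == 0)) amp[amp == 0] <- runif(sum(amp == 0))
  structure(list(kind = "irregular", N = N, M = as.integer(M),
                 centers = centers, amplitudes = amp,
                 beta = rowSums(amp), spec = spec, seed = seed),
            class = "input_ensemble")
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat(sprintf("<%s input ensemble>  N = %d, M = %d, sigma = %g m, r_av = %g 1/s, L = %g m\n",
              x$kind, x$N, x$M, x$spec$sigma, x$spec$r_av, x$spec$L))
  invisible(x)
}

# row indices into `centers` for neuron i
fieldRows <- function(ensemble, i) {
  if (ensemble$kind == "regular") i else ((i - 1) * ensemble$M + seq_len(ensemble$M))
}

#' Input firing rate at a position
#'
#' Evaluates neuron \code{i}'s tuning curve
#' \eqn{\Psi_i(x) = \beta_i^{-1}\sum_j A_{ij} G(|x - r_{ij}|)} with periodic
#' (minimal-image) distances.
#'
#' @param ensemble an input ensemble
#' @param neuron input index
#' @param x positions: length-2 vector or 2-column matrix
#' @return rates (1/s)
#' @export
rateAt <- function(ensemble, neuron, x) {
  if (neuron < 1 || neuron > ensemble$N) stop("neuron index out of range")
  x <- rbind(x)
  sp <- ensemble$spec
  peak <- sp$L^2 * sp$r_av / (2 * pi * sp$sigma^2)
  rows <- fieldRows(ensemble, neuron)
  amps <- ensemble$amplitudes[neuron, ]
  acc <- 0
  for (j in seq_along(rows)) {
    r <- ensemble$centers[rows[j], ]
    acc <- acc + amps[j] *
      periodicGaussian(x[, 1] - r[1], x[, 2] - r[2], sp$sigma, sp$L)
  }
  as.vector(peak * acc / ensemble$beta[neuron])
}

#' Firing-rate map of one input
#'
#' [rateAt()] evaluated at every bin center \eqn{((i+1/2)L/n, (j+1/2)L/n)}.
#'
#' @inheritParams rateAt
#' @param n_bins grid resolution per axis (>= 8)
#' @return a [map2d()] (row index = x, column index = y, origin lower-left)
#' @export
rateMap <- function(ensemble, neuron, n_bins = 100) {
  if (n_bins < 8) stop("n_bins must be >= 8")
  L <- ensemble$spec$L
  cc <- (seq_len(n_bins) - 0.5) / n_bins * L
  xy <- as.matrix(expand.grid(x = cc, y = cc))
  map2d(matrix(rateAt(ensemble, neuron, xy), n_bins, n_bins), L)
}

#' Rates of all inputs along a set of positions
#'
#' Vectorized evaluation used by the spiking simulator: one row per
#' position, one column per input neuron.
#'
#' @param ensemble an input ensemble
#' @param xy 2-column matrix of positions
#' @return \code{nrow(xy) x N} rate matrix (1/s)
#' @export
ensembleRates <- function(ensemble, xy) {
  xy <- rbind(xy)
  sp <- ensemble$spec
  peak <- sp$L^2 * sp$r_av / (2 * pi * sp$sigma^2)
  out <- matrix(0, nrow(xy), ensemble$N)
  for (i in seq_len(ensemble$N)) {
    rows <- fieldRows(ensemble, i)
    amps <- ensemble$amplitudes[i, ]
    acc <- 0
    for (j in seq_along(rows)) {
      r <- ensemble$centers[rows[j], ]
      acc <- acc + amps[j] *
        periodicGaussian(xy[, 1] - r[1], xy[, 2] - r[2], sp$sigma, sp$L)
    }
    out[, i] <- peak * acc / ensemble$beta[i]
  }
  out
}

# Analytic torus Fourier coefficients of the tuning curves.
# modes: data.frame(n1, n2) of integer frequencies; coefficient
# Psi_hat_i[n] = int Psi_i(x) exp(-2*pi*j n.x/L) dx
#              = Ghat(|n|/L) / beta_i * sum_m A_im exp(-2*pi*j n.r_im/L)
# with Ghat(k) = L^2 r_av exp(-(2*pi*k)^2 sigma^2 / 2).
# Returns a (nmodes x N) complex matrix.
inputModeCoefficients <- function(ensemble, modes) {
  sp <- ensemble$spec; L <- sp$L
  kabs <- sqrt(modes$n1^2 + modes$n2^2) / L
  Ghat <- L^2 * sp$r_av * exp(-(2 * pi * kabs)^2 * sp$sigma^2 / 2)
  ctr <- ensemble$centers
  E <- exp(-2i * pi * (outer(modes$n1, ctr[, 1]) +
                       outer(modes$n2, ctr[, 2])) / L)
  if (ensemble$kind == "regular") {
    A <- E
  } else {
    M <- ensemble$M; N <- ensemble$N
    amp <- as.vector(t(ensemble$amplitudes))      # row (i-1)*M+m
    E <- sweep(E, 2, amp, "*")
    A <- matrix(0 + 0i, nrow(modes), N)
    for (m in seq_len(M)) A <- A + E[, (seq_len(N) - 1) * M + m, drop = FALSE]
    A <- sweep(A, 2, ensemble$beta, "/")
  }
  sweep(A, 1, Ghat, "*")
}

# integer torus modes up to |n| <= n_cut (square block, k = |n|/L)
torusModes <- function(n_cut) {
  expand.grid(n1 = -n_cut:n_cut, n2 = -n_cut:n_cut)
}
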