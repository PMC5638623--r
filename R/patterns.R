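#' Square spatial map
#'
#' Container for weight patterns and firing-rate maps: a square matrix of
#' values on the periodic arena, row index = x, column index = y, origin at
#' the lower-left, bin spacing \code{L/n}.
#'
#' @param values square numeric matrix
#' @param L physical side length (m)
#' @export
map2d <- function(values, L) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("map must be square")
  if (any(!is.finite(values))) stop("map values must be finite")
  structure(list(values = values, n = nrow(values), L = L),
            class = "map2d")
}

#' @export
print.map2d <- function(x, ...) {
  cat(sprintf("<map2d>  %d x %d bins over [0, %g m)^2, range [%.4g, %.4g]\n",
              x$n, x$n, x$L, min(x$values), max(x$values)))
  invisible(x)
}

#' Arrange a weight vector on its lattice as a map
#'
#' For a regular ensemble the weight of input \code{i} lives at its
#' receptive-field center; the \eqn{\sqrt N \times \sqrt N} arrangement is
#' the weight pattern analyzed for grid structure.
#'
#' @param w weight vector (length a perfect square)
#' @param L arena side (m)
#' @export
weightMap <- function(w, L) {
  s <- round(sqrt(length(w)))
  if (s * s != length(w)) stop("weight vector length is not a perfect square")
  map2d(matrix(w, s, s), L)
}

# periodic bilinear interpolation of a square matrix sampled at
# (i-1)*L/n; x, y in meters (any real; wrapped)
bilinearPeriodic <- function(M, x, y, L) {
  n <- nrow(M)
  xs <- x / L * n; ys <- y / L * n
  i0 <- floor(xs); fx <- xs - i0
  j0 <- floor(ys); fy <- ys - j0
  i0 <- i0 %% n; j0 <- j0 %% n
  i1 <- (i0 + 1) %% n; j1 <- (j0 + 1) %% n
  M[cbind(i0 + 1, j0 + 1)] * (1 - fx) * (1 - fy) +
    M[cbind(i1 + 1, j0 + 1)] * fx * (1 - fy) +
    M[cbind(i0 + 1, j1 + 1)] * (1 - fx) * fy +
    M[cbind(i1 + 1, j1 + 1)] * fx * fy
}

#' Periodic spatial autocorrelogram
#'
#' Torus Pearson autocorrelation of the map at all lags (computed
#' spectrally): exactly 1 at zero lag, symmetric under lag negation.
#'
#' @param map a [map2d()]
#' @return a [map2d()] of correlations in \eqn{[-1, 1]} (lag origin at
#'   index (1,1))
#' @export
autocorrelogram <- function(map) {
  m <- map$values - mean(map$values)
  ss <- sum(m^2)
  if (ss == 0) stop("constant map: autocorrelation undefined")
  F <- fft(m)
  ac <- Re(fft(Conj(F) * F, inverse = TRUE)) / map$n^2 / ss
  map2d(ac, map$L)
}

#' Grid spatial scale (dominant spatial frequency)
#'
#' Radial amplitude profile of the 2D Fourier transform (angular average
#' over frequency magnitude bins of width \code{1/L}); the grid scale is
#' the profile's global maximum, zero frequency excluded. Invariant under
#' additive and positive multiplicative rescaling of the map.
#'
#' @param map a [map2d()]
#' @return dominant frequency (cycles/m)
#' @export
gridScale <- function(map) {
  m <- map$values - mean(map$values)
  if (all(m == 0)) stop("constant map: scale undefined")
  A <- Mod(fft(m))
  fr <- fftFrequencies(map$n, map$L)
  kk <- sqrt(outer(fr^2, fr^2, "+"))
  kb <- round(kk * map$L) / map$L          # bins of width 1/L
  prof <- tapply(as.vector(A), as.vector(kb), mean)
  prof <- prof[-1]                          # drop k = 0
  as.numeric(names(prof))[which.max(prof)]
}

fftFrequencies <- function(n, L) {
  c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / L
}

# annulus sample points (radii R/2..R, n_r x n_phi polar grid) of a
# periodic correlogram, plus its rotations
annulusSamples <- function(ac, L, R, phi_deg, n_r = 12, n_phi = 90) {
  # radii sqrt-spaced: uniform sampling density per unit AREA, matching
  # the pixel-based ring extraction of the standard gridness procedure
  rr <- sqrt(seq((R / 2)^2, R^2, length.out = n_r))
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  pts <- expand.grid(r = rr, p = ph)
  a <- pts$p + phi_deg * pi / 180
  bilinearPeriodic(ac, pts$r * cos(a), pts$r * sin(a), L)
}

#' Gridness score
#'
#' Rotational-symmetry statistic of the spatial autocorrelogram: with
#' \eqn{\rho(\varphi)} the Pearson correlation between an annulus of the
#' correlogram (inner radius \eqn{R/2}, outer radius \eqn{R}) and the same
#' annulus rotated by \eqn{\varphi} degrees,
#' \deqn{g = \tfrac12[\rho(60) + \rho(120)] -
#'   \tfrac13[\rho(30) + \rho(90) + \rho(150)],}
#' maximized over 24 outer radii \eqn{R} between \eqn{0.7/k_{max}} and
#' \eqn{2.5/k_{max}} (lengths in meters; \eqn{k_{max}} is the pattern
#' frequency from [gridScale()]). Annuli are sampled on a polar grid
#' (radii spaced uniformly in area, as in the pixel-ring construction)
#' with periodic bilinear interpolation, so rotations are exact in angle. A
#' triangular lattice scores well above 1; a square lattice scores
#' negative; noise scores near 0.
#'
#' @param map a [map2d()]
#' @param k_max optional pattern frequency (cycles/m); estimated by
#'   [gridScale()] when missing
#' @param n_radii number of candidate outer radii
#' @return list with \code{gridness}, \code{ring_radius} (the maximizing
#'   outer radius, m) and \code{scale_freq}
#' @export
gridness <- function(map, k_max = NULL, n_radii = 24) {
  if (is.null(k_max)) k_max <- gridScale(map)
  ac <- autocorrelogram(map)$values
  Rs <- seq(0.7 / k_max, 2.5 / k_max, length.out = n_radii)
  best <- -Inf; bestR <- NA_real_
  for (R in Rs) {
    base <- annulusSamples(ac, map$L, R, 0)
    rho <- vapply(c(30, 60, 90, 120, 150), function(ang)
      stats::cor(base, annulusSamples(ac, map$L, R, ang)), numeric(1))
    g <- mean(rho[c(2, 4)]) - mean(rho[c(1, 3, 5)])
    if (g > best) { best <- g; bestR <- R }
  }
  list(gridness = best, ring_radius = bestR, scale_freq = k_max)
}

# local maxima of a periodic matrix (8-neighborhood)
localMaxima <- function(M) {
  n <- nrow(M)
  sh <- function(di, dj) M[(seq_len(n) - 1 + di) %% n + 1,
                           (seq_len(n) - 1 + dj) %% n + 1]
  ok <- M > sh(1, 0) & M >= sh(-1, 0) & M > sh(0, 1) & M >= sh(0, -1) &
        M > sh(1, 1) & M >= sh(-1, -1) & M > sh(1, -1) & M >= sh(-1, 1)
  which(ok, arr.ind = TRUE)
}

#' Grid orientation
#'
#' Angle (degrees, reported modulo 60) between the horizontal axis and the
#' autocorrelogram peak closest to the center within the first quadrant
#' (x > 0, y >= 0).
#'
#' @param map a [map2d()]
#' @return orientation in \eqn{[0, 60)} degrees
#' @export
gridOrientation <- function(map) {
  ac <- autocorrelogram(map)
  pk <- correlogramPeaks(ac)
  q1 <- pk[pk[, "x"] > 1e-9 & pk[, "y"] >= -1e-9, , drop = FALSE]
  if (nrow(q1) == 0) stop("no off-center correlogram peak found")
  i <- which.min(q1[, "r"])
  (atan2(q1[i, "y"], q1[i, "x"]) * 180 / pi) %% 60
}

# off-center peaks of a correlogram as centered coordinates
correlogramPeaks <- function(ac) {
  n <- ac$n; L <- ac$L
  idx <- localMaxima(ac$values)
  x <- torusDelta((idx[, 1] - 1) / n * L, L)
  y <- torusDelta((idx[, 2] - 1) / n * L, L)
  r <- sqrt(x^2 + y^2)
  keep <- r > 1e-9
  cbind(x = x[keep], y = y[keep], r = r[keep])
}

#' Ideal triangular (grid) pattern
#'
#' Sum of three plane-wave cosines with wave vectors of magnitude
#' \code{k} spaced 60 degrees apart — the canonical grid fixture, also used
#' as the reference pattern for phase estimation. The \code{orientation}
#' refers to a lattice axis (the direction of the nearest-neighbor peaks,
#' as measured by [gridOrientation()]); the wave vectors lie 30 degrees
#' away from the lattice axes.
#'
#' @param n bins per axis
#' @param L arena side (m)
#' @param k lattice frequency (cycles/m)
#' @param orientation lattice-axis angle, degrees; 0 puts a row of peaks
#'   along the x axis
#' @param phase 2D spatial offset (m) of a lattice peak from the origin
#' @export
makeTriangularPattern <- function(n, L, k, orientation = 0,
                                  phase = c(0, 0)) {
  th <- (orientation + 30) * pi / 180 + c(0, pi / 3, 2 * pi / 3)
  cc <- (seq_len(n) - 1) / n * L
  xy <- expand.grid(x = cc, y = cc)
  vals <- 0
  for (t in th)
    vals <- vals + cos(2 * pi * k * ((xy$x - phase[1]) * cos(t) +
                                     (xy$y - phase[2]) * sin(t)))
  map2d(matrix(vals, n, n), L)
}

#' Ideal square-lattice pattern
#'
#' Two orthogonal cosines; scores negative gridness (the 90-degree
#' correlation enters with negative weight).
#'
#' @inheritParams makeTriangularPattern
#' @export
makeSquarePattern <- function(n, L, k, orientation = 0, phase = c(0, 0)) {
  th <- orientation * pi / 180 + c(0, pi / 2)
  cc <- (seq_len(n) - 1) / n * L
  xy <- expand.grid(x = cc, y = cc)
  vals <- 0
  for (t in th)
    vals <- vals + cos(2 * pi * k * ((xy$x - phase[1]) * cos(t) +
                                     (xy$y - phase[2]) * sin(t)))
  map2d(matrix(vals, n, n), L)
}

#' Grid spatial phase
#'
#' Offset of the lattice relative to the arena origin: the map is
#' cross-correlated (periodically, spectral method) with a reference
#' triangular pattern at the same scale and orientation anchored at the
#' origin, and the phase is the minimal-image location of the
#' cross-correlation peak nearest the center.
#'
#' @param map a [map2d()]
#' @param scale_freq,orientation optional; estimated from the map when
#'   missing
#' @return 2D offset (m), within one lattice cell around 0
#' @export
gridPhase <- function(map, scale_freq = NULL, orientation = NULL) {
  if (is.null(scale_freq)) scale_freq <- gridScale(map)
  if (is.null(orientation)) orientation <- gridOrientation(map)
  ref <- makeTriangularPattern(map$n, map$L, scale_freq, orientation)
  a <- map$values - mean(map$values)
  b <- ref$values - mean(ref$values)
  xc <- Re(fft(Conj(fft(b)) * fft(a), inverse = TRUE))
  pkidx <- localMaxima(xc)
  x <- torusDelta((pkidx[, 1] - 1) / map$n * map$L, map$L)
  y <- torusDelta((pkidx[, 2] - 1) / map$n * map$L, map$L)
  i <- which.min(x^2 + y^2)
  c(x = x[i], y = y[i])
}

#' Output firing-rate map from learned weights
#'
#' \deqn{\Psi^{out}(x) = r_0 + \int dy\, K_{sp}(|y|)
#'   \sum_i w_i \Psi_i(x - y):}
#' the weighted sum of the input maps convolved with the spatial kernel
#' (accounting for the average effect of the temporal adaptation on the
#' output rate). The periodic convolution is evaluated spectrally with the
#' closed-form Hankel transform of \eqn{K_{sp}} — the kernel's integrable
#' pointwise singularity never needs rasterizing.
#'
#' @param ensemble input ensemble
#' @param weights synaptic weights (length N)
#' @param kernel adaptation kernel
#' @param v running speed (m/s)
#' @param r0 baseline rate (1/s)
#' @param n_bins output resolution
#' @param k_cut Fourier cut-off (cycles/m)
#' @return a [map2d()] of output rates (1/s; the linear estimate may dip
#'   below zero)
#' @export
outputRateMap <- function(ensemble, weights, kernel = adaptationKernel(),
                          v = 0.25, r0 = 0, n_bins = 100, k_cut = 8) {
  if (length(weights) != ensemble$N) stop("weights length must equal N")
  L <- ensemble$spec$L
  modes <- torusModes(ceiling(k_cut * L))
  kabs <- sqrt(modes$n1^2 + modes$n2^2) / L
  A <- inputModeCoefficients(ensemble, modes)
  fhat <- as.vector(A %*% weights) *
    2 * pi * spatialKernelHankel(kernel, v, kabs)
  Fm <- matrix(0 + 0i, n_bins, n_bins)
  ii <- (modes$n1 %% n_bins) + 1
  jj <- (modes$n2 %% n_bins) + 1
  for (q in seq_len(nrow(modes)))
    Fm[ii[q], jj[q]] <- Fm[ii[q], jj[q]] + fhat[q]
  map2d(Re(fft(Fm, inverse = TRUE)) / L^2 + r0, L)
}
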