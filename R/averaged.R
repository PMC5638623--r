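#' Effective decay and drive rates of the averaged weight dynamics
#'
#' Averaging the STDP rule over spike statistics yields the linear drift
#' \eqn{\eta^{-1} \dot{\bar w}_i = \sum_j C_{ij}\bar w_j - a \bar w_i + b}
#' with
#' \deqn{a = r_{av}\left[\alpha - \int W(s) K(-s)\,ds\right], \qquad
#'       b = r_{av}\,(W_{tot}\, r_0 + \beta).}
#' The window--kernel overlap integral is evaluated in closed form: for a
#' kernel component \eqn{c\,e^{-t/\tau}},
#' \eqn{\int_0^\infty W(-t)\,c\,e^{-t/\tau} dt =
#' \frac{W_{tot}}{2\tau_W}\, \frac{c}{1/\tau_W + 1/\tau}.}
#'
#' @param plasticity [plasticityParams()]
#' @param kernel adaptation kernel
#' @param neuron [neuronParams()] (supplies the baseline rate \code{r0})
#' @param r_av spatial-average input rate (1/s)
#' @return list with elements \code{a}, \code{b}, \code{overlap} (all 1/s)
#' @export
deriveAB <- function(plasticity, kernel, neuron, r_av) {
  ov <- windowKernelOverlap(plasticity, kernel)
  list(a = r_av * (plasticity$alpha - ov),
       b = r_av * (plasticity$w_tot * neuron$r0 + plasticity$beta),
       overlap = ov)
}

# closed-form integral of W(s) K(-s) over s (only s < 0 contributes since
# K is causal and W symmetric)
windowKernelOverlap <- function(plasticity, kernel) {
  W0 <- plasticity$w_tot / (2 * plasticity$tau_w)
  sum(W0 * kernel$coef / (1 / plasticity$tau_w + 1 / kernel$tau))
}

#' Input-correlation function for regular Gaussian inputs (closed form)
#'
#' For single-field Gaussian inputs, the correlation between two inputs at
#' receptive-field distance \code{u} reduces to a radial integral over the
#' kernel,
#' \deqn{C(u) = \frac{W_{tot} L^2 r_{av}^2}{4\pi\sigma^2}
#'   \int_0^\infty d\tau\, K(\tau)\,
#'   e^{-\frac{u^2 + (\tau v)^2}{4\sigma^2}}\,
#'   I_0\!\left(\frac{u\,\tau v}{2\sigma^2}\right),}
#' evaluated by Gauss--Legendre quadrature (the printed Bessel argument is
#' negative, but \eqn{I_0} is even, so only its magnitude matters). The
#' result is a Mexican-hat profile: positive at short distances (attraction),
#' negative at intermediate distances (repulsion).
#'
#' @param u receptive-field distances (m), \code{u >= 0}; vectorized
#' @param spec [gaussianFieldSpec()]
#' @param kernel adaptation kernel
#' @param v running speed (m/s)
#' @param w_tot STDP window integral (s)
#' @param quad optional quadrature rule (list \code{x, w}) from
#'   \code{kernelQuadrature}
#' @return correlations (1/s)
#' @export
correlationRadial <- function(u, spec, kernel, v = 0.25, w_tot = 1,
                              quad = NULL) {
  if (any(u < 0)) stop("u must be non-negative")
  if (is.null(quad)) quad <- kernelQuadrature(kernel)
  sg2 <- spec$sigma^2
  pref <- w_tot * spec$L^2 * spec$r_av^2 / (4 * pi * sg2)
  Kt <- kernelValue(kernel, quad$x)
  vapply(u, function(uu) {
    # exp(-(u^2+(tv)^2)/4s^2) I0(u t v/2s^2) = exp(-(u-tv)^2/4s^2) I0scaled
    x <- uu * quad$x * v / (2 * sg2)
    f <- Kt * exp(-((uu - quad$x * v)^2) / (4 * sg2)) *
      besselI(x, 0, expon.scaled = TRUE)
    pref * sum(quad$w * f)
  }, numeric(1))
}

#' Input-correlation model from an ensemble
#'
#' Builds the \eqn{N \times N} correlation matrix
#' \deqn{C_{ij} = \frac{W_{tot}}{L^2} \int_0^\infty d\tau\, K(\tau)
#'   \oint_{|z| = \tau v} dz\; \Psi_i \star \Psi_j \big|_z}
#' (the spatial cross-correlation of the two tuning curves averaged over
#' circles of radius \eqn{\tau v}, weighted by the kernel).
#'
#' Three construction routes are available:
#' \describe{
#'   \item{\code{"radial"}}{regular ensembles only: the Gaussian closed form
#'     [correlationRadial()] evaluated at the pairwise minimal-image
#'     distances. Fast and exact up to quadrature.}
#'   \item{\code{"correlogram"}}{fully general: periodic cross-correlograms
#'     of the gridded rate maps (spectral method), circle-averaged by
#'     periodic bilinear interpolation at \code{n_angles} angles per radius.
#'     For regular ensembles one auto-correlogram is reused for all pairs.}
#'   \item{\code{"fourier"}}{fully general and fast: the same operator
#'     assembled in the torus Fourier basis from the analytic input mode
#'     coefficients and the Hankel-transformed kernel (mathematically
#'     identical to \code{"correlogram"}, no gridding error).}
#' }
#'
#' @param ensemble input ensemble
#' @param kernel adaptation kernel
#' @param v running speed (m/s)
#' @param w_tot STDP window integral (s)
#' @param method one of \code{"radial"}, \code{"correlogram"},
#'   \code{"fourier"} (default: \code{"radial"} for regular ensembles,
#'   \code{"fourier"} otherwise)
#' @param n_bins correlogram grid resolution (\code{"correlogram"} only)
#' @param n_angles circle-average resolution (\code{"correlogram"} only)
#' @param k_cut Fourier-mode cut-off, cycles per \code{L}
#'   (\code{"fourier"} only); modes beyond it are negligible for
#'   \eqn{\sigma \gtrsim L/(2\pi k_{cut})}
#' @return a \code{correlation_model}: list with the \code{matrix} (N x N,
#'   1/s), the generating \code{ensemble}, \code{kernel}, \code{v},
#'   \code{w_tot} and \code{method}
#' @export
correlationMatrix <- function(ensemble, kernel = adaptationKernel(),
                              v = 0.25, w_tot = 1,
                              method = NULL, n_bins = 128, n_angles = 256,
                              k_cut = 8) {
  if (is.null(method))
    method <- if (ensemble$kind == "regular") "radial" else "fourier"
  C <- switch(method,
    radial = corrMatrixRadial(ensemble, kernel, v, w_tot),
    correlogram = corrMatrixCorrelogram(ensemble, kernel, v, w_tot,
                                        n_bins, n_angles),
    fourier = corrMatrixFourier(ensemble, kernel, v, w_tot, k_cut),
    stop("unknown method"))
  structure(list(matrix = C, ensemble = ensemble, kernel = kernel,
                 v = v, w_tot = w_tot, method = method),
            class = "correlation_model")
}

corrMatrixRadial <- function(ensemble, kernel, v, w_tot) {
  if (ensemble$kind != "regular")
    stop("radial closed form applies to regular ensembles only")
  L <- ensemble$spec$L
  ctr <- ensemble$centers
  dx <- torusDelta(outer(ctr[, 1], ctr[, 1], "-"), L)
  dy <- torusDelta(outer(ctr[, 2], ctr[, 2], "-"), L)
  d <- sqrt(dx^2 + dy^2)
  ud <- sort(unique(as.vector(d)))
  cv <- correlationRadial(ud, ensemble$spec, kernel, v, w_tot)
  matrix(cv[match(as.vector(d), ud)], ensemble$N, ensemble$N)
}

corrMatrixFourier <- function(ensemble, kernel, v, w_tot, k_cut) {
  L <- ensemble$spec$L
  modes <- torusModes(ceiling(k_cut * L))
  kabs <- sqrt(modes$n1^2 + modes$n2^2) / L
  A <- inputModeCoefficients(ensemble, modes)
  D <- w_tot * spatialKernelHankel(kernel, v, kabs) / L^4
  C <- crossprod(Conj(A), A * D)
  stopifnot(max(abs(Im(C))) < 1e-8 * max(abs(Re(C))))
  Re(C)
}

corrMatrixCorrelogram <- function(ensemble, kernel, v, w_tot,
                                  n_bins, n_angles) {
  sp <- ensemble$spec; L <- sp$L; N <- ensemble$N
  if (sp$sigma < 2 * L / n_bins)
    warning("sigma below 2 bins; correlogram resolution is too coarse")
  quad <- kernelQuadrature(kernel)
  Kw <- quad$w * kernelValue(kernel, quad$x)
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ca <- cos(ang); sa <- sin(ang)
  circleAvgAll <- function(cgram, u) {
    # mean of the periodic correlogram over circles of radius tau*v
    # centered at each row of u, integrated against the kernel
    out <- numeric(nrow(u))
    for (q in seq_along(quad$x)) {
      r <- quad$x[q] * v
      s <- 0
      for (aidx in seq_len(n_angles))
        s <- s + bilinearPeriodic(cgram, u[, 1] + r * ca[aidx],
                                  u[, 2] + r * sa[aidx], L)
      out <- out + Kw[q] * s / n_angles
    }
    out
  }
  binArea <- (L / n_bins)^2
  if (ensemble$kind == "regular") {
    # translation invariance: one auto-correlogram serves all pairs
    m0 <- rateMapValues(ensemble, 1, n_bins)
    F0 <- fft(m0)
    cgram <- Re(fft(Conj(F0) * F0, inverse = TRUE)) / n_bins^2 * binArea
    ctr <- ensemble$centers
    dx <- torusDelta(outer(ctr[, 1], ctr[, 1], "-"), L)
    dy <- torusDelta(outer(ctr[, 2], ctr[, 2], "-"), L)
    u <- cbind(as.vector(dx), as.vector(dy))
    uk <- paste(round(u[, 1], 10), round(u[, 2], 10))
    uniq <- !duplicated(uk)
    vals <- circleAvgAll(cgram, u[uniq, , drop = FALSE])
    C <- matrix(vals[match(uk, uk[uniq])], N, N) * w_tot / L^2
  } else {
    Fs <- vector("list", N)
    for (i in seq_len(N)) Fs[[i]] <- fft(rateMapValues(ensemble, i, n_bins))
    C <- matrix(0, N, N)
    origin <- matrix(0, 1, 2)
    for (i in seq_len(N)) for (j in i:N) {
      cg <- Re(fft(Conj(Fs[[i]]) * Fs[[j]], inverse = TRUE)) /
        n_bins^2 * binArea
      C[i, j] <- C[j, i] <- circleAvgAll(cg, origin) * w_tot / L^2
    }
  }
  C
}

# rate map values on the FFT grid (bin origin at 0, spacing L/n)
rateMapValues <- function(ensemble, neuron, n_bins) {
  L <- ensemble$spec$L
  cc <- (seq_len(n_bins) - 1) / n_bins * L
  xy <- as.matrix(expand.grid(x = cc, y = cc))
  matrix(rateAt(ensemble, neuron, xy), n_bins, n_bins)
}

#' Weight-normalization level and time scale
#'
#' The mean weight obeys
#' \eqn{\eta^{-1}\dot w_{av} = (N C_{av} - a) w_{av} + b} with
#' \eqn{C_{av} = N^{-2}\sum_{ij} C_{ij}}; for \eqn{N C_{av} < a} it relaxes
#' with time constant \eqn{\tau_{av} = 1/(\eta(a - N C_{av}))} to
#' \eqn{w_{av}^\infty = b/(a - N C_{av})}.
#'
#' @param model a \code{correlation_model} (or a plain matrix)
#' @param a,b averaged-dynamics rates (1/s), see [deriveAB()]
#' @param eta learning rate
#' @return list with \code{w_av_inf}, \code{tau_av} (s), \code{c_av},
#'   \code{n_c_av}
#' @export
normalizationQuantities <- function(model, a, b, eta) {
  C <- if (inherits(model, "correlation_model")) model$matrix else model
  N <- nrow(C)
  c_av <- mean(C)
  denom <- a - N * c_av
  if (denom <= 0)
    stop("a - N*C_av <= 0: weight normalization is unstable")
  list(w_av_inf = b / denom, tau_av = 1 / (eta * denom),
       c_av = c_av, n_c_av = N * c_av)
}

#' Integrate the averaged weight dynamics
#'
#' Forward-Euler integration of
#' \eqn{\eta^{-1}\dot{\bar w} = C\bar w - a\bar w + b} with projection onto
#' \eqn{w \ge 0} after every step (projected Euler). The non-negativity
#' clamp is the nonlinearity that selects the triangular symmetry; with
#' \code{clamp = FALSE} the system is exactly linear and all Fourier modes
#' grow independently.
#'
#' For regular lattice ensembles the matrix is block-circulant and the
#' product \eqn{C w} is computed by 2D FFT (\code{operator = "fft"}), which
#' makes large-\code{N} runs cheap; \code{operator = "matrix"} uses the
#' dense matrix; \code{operator = "modes"} applies the Fourier-mode Gram
#' factorization (irregular ensembles) without materializing \eqn{C}.
#'
#' @param model \code{correlation_model}, or (for \code{operator="modes"})
#'   the list returned by [modeOperator()]
#' @param a,b,eta averaged-dynamics parameters
#' @param w_init initial weights (length N)
#' @param t_end integration end time (s)
#' @param dt_euler step (s), default 50
#' @param checkpoints times at which to record weights (defaults to t_end)
#' @param clamp apply the non-negativity bound?
#' @param operator \code{"auto"}, \code{"matrix"}, \code{"fft"} or
#'   \code{"modes"}
#' @param diverge_tol abort when \code{max|w|} exceeds this (ignored when
#'   \code{clamp = FALSE}, where exponential growth is expected)
#' @return list with \code{w} (final), \code{w_hist} (checkpoints x N),
#'   \code{checkpoints}, \code{t_end}
#' @export
integrateAveraged <- function(model, a, b, eta, w_init, t_end,
                              dt_euler = 50, checkpoints = NULL,
                              clamp = TRUE, operator = "auto",
                              diverge_tol = 1e3) {
  n_steps <- round(t_end / dt_euler)
  if (is.null(checkpoints)) checkpoints <- t_end
  cp_steps <- pmax(1L, pmin(as.integer(round(sort(checkpoints) / dt_euler)),
                            n_steps))
  applyC <- makeOperatorFun(model, operator)
  w <- w_init
  lam_scale <- abs(a) + 1
  if (eta * dt_euler * lam_scale > 0.5)
    warning("dt_euler may violate explicit-Euler stability")
  w_hist <- matrix(NA_real_, length(cp_steps), length(w))
  next_cp <- 1L
  guard <- diverge_tol * max(abs(b / a), 1e-3)
  for (s in seq_len(n_steps)) {
    w <- w + eta * dt_euler * (applyC(w) - a * w + b)
    if (clamp) {
      w[w < 0] <- 0
      if (max(w) > guard)
        stop("averaged dynamics diverged (|w| > ", signif(guard, 3), ")")
    }
    while (next_cp <= length(cp_steps) && cp_steps[next_cp] == s) {
      w_hist[next_cp, ] <- w
      next_cp <- next_cp + 1L
    }
  }
  list(w = w, w_hist = w_hist, checkpoints = cp_steps * dt_euler,
       t_end = n_steps * dt_euler)
}

makeOperatorFun <- function(model, operator) {
  if (inherits(model, "mode_operator")) {
    # real/imaginary split: four real GEMVs instead of complex arithmetic
    Ar <- Re(model$A); Ai <- Im(model$A); d <- model$d
    tAr <- t(Ar); tAi <- t(Ai)
    return(function(w) {
      yr <- d * (Ar %*% w); yi <- d * (Ai %*% w)
      as.vector(tAr %*% yr + tAi %*% yi)
    })
  }
  stopifnot(inherits(model, "correlation_model"))
  ens <- model$ensemble
  if (operator == "auto")
    operator <- if (ens$kind == "regular" &&
                    nrow(ens$centers) == round(sqrt(ens$N))^2) "fft"
                else "matrix"
  if (operator == "matrix") {
    C <- model$matrix
    return(function(w) as.vector(C %*% w))
  }
  if (operator == "fft") {
    s <- round(sqrt(ens$N))
    # eigenvalue map of the block-circulant matrix: 2D FFT of first row
    ev <- Re(fft(matrix(model$matrix[1, ], s, s)))
    return(function(w)
      as.vector(Re(fft(fft(matrix(w, s, s)) * ev, inverse = TRUE))) / s^2)
  }
  stop("unknown operator")
}

#' Fourier-mode Gram factorization of the correlation operator
#'
#' Returns the pieces needed to apply \eqn{C w} without materializing the
#' \eqn{N \times N} matrix: \eqn{C = A^H \mathrm{diag}(d) A} with
#' \eqn{A[n, i] = \hat\Psi_i[n]} (analytic torus Fourier coefficients of
#' the tuning curves) and
#' \eqn{d[n] = W_{tot} \tilde K_{sp}(|n|/L) / L^4}.
#'
#' @inheritParams correlationMatrix
#' @export
modeOperator <- function(ensemble, kernel = adaptationKernel(),
                         v = 0.25, w_tot = 1, k_cut = 8) {
  L <- ensemble$spec$L
  modes <- torusModes(ceiling(k_cut * L))
  kabs <- sqrt(modes$n1^2 + modes$n2^2) / L
  # real tuning curves: Psi_hat(-n) = conj(Psi_hat(n)), so one half-plane
  # of the frequency disk suffices with doubled weights
  keep <- kabs <= k_cut &
    (modes$n1 > 0 | (modes$n1 == 0 & modes$n2 >= 0))
  modes <- modes[keep, ]; kabs <- kabs[keep]
  mult <- ifelse(modes$n1 == 0 & modes$n2 == 0, 1, 2)
  A <- inputModeCoefficients(ensemble, modes)
  structure(list(A = A,
                 d = mult * w_tot * spatialKernelHankel(kernel, v, kabs) / L^4,
                 modes = modes, ensemble = ensemble, kernel = kernel,
                 v = v, w_tot = w_tot),
            class = "mode_operator")
}
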