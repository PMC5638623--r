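#' Spectrum configuration
#'
#' Bundles everything the dispersion relation needs: input density
#' \eqn{\rho = N/L^2}, the Gaussian field spec, the temporal kernel, the
#' running speed, the STDP window integral and the effective decay rate
#' \code{a}.
#'
#' @param rho input receptive-field density (1/m^2)
#' @param spec [gaussianFieldSpec()]
#' @param kernel adaptation kernel (or AHP equivalent kernel)
#' @param v running speed (m/s)
#' @param w_tot STDP window integral (s)
#' @param a effective weight-decay rate (1/s)
#' @export
spectrumConfig <- function(rho = 900, spec = gaussianFieldSpec(),
                           kernel = adaptationKernel(), v = 0.25,
                           w_tot = 1, a = 1.1) {
  if (!(rho > 0)) stop("rho must be positive")
  structure(list(rho = rho, spec = spec, kernel = kernel, v = v,
                 w_tot = w_tot, a = a),
            class = "spectrum_config")
}

# Hankel transform of the Gaussian tuning curve, k in cycles/m:
# Gtilde(k) = (L^2 r_av / 2 pi) exp(-(2 pi k)^2 sigma^2 / 2)
gaussianHankel <- function(spec, k) {
  spec$L^2 * spec$r_av / (2 * pi) * exp(-(2 * pi * k)^2 * spec$sigma^2 / 2)
}

#' Eigenvalue spectrum of the averaged weight dynamics
#'
#' The dispersion relation of the linearized dynamics,
#' \deqn{\lambda(k) = \rho\, W_{tot}\, \frac{4\pi^2}{L^2}\,
#'   \tilde G^2(k)\, \tilde K_{sp}(k) - a, \qquad k \ne 0,}
#' with \eqn{\tilde G} and \eqn{\tilde K_{sp}} the zeroth-order Hankel
#' transforms of the Gaussian tuning curve and of the spatial kernel
#' (\code{k} in cycles/m; the transforms carry the \eqn{2\pi} internally).
#' A positive global maximum at \eqn{k_{max} > 0} is the Turing condition
#' for periodic pattern formation; Fourier modes grow as
#' \eqn{e^{\eta \lambda(k) t}}.
#'
#' @param cfg a [spectrumConfig()]
#' @param k spatial frequencies (cycles/m), \code{k > 0}
#' @return eigenvalues (1/s)
#' @export
eigenvalueSpectrum <- function(cfg, k) {
  if (any(k <= 0)) stop("k must be positive (k = 0 governs normalization)")
  L <- cfg$spec$L
  cfg$rho * cfg$w_tot * 4 * pi^2 / L^2 * gaussianHankel(cfg$spec, k)^2 *
    spatialKernelHankel(cfg$kernel, cfg$v, k) - cfg$a
}

#' Critical frequency, largest eigenvalue and structure-formation time
#'
#' Maximizes \eqn{\lambda(k)} over a frequency grid with parabolic
#' refinement. When the supremum over \eqn{k > 0} sits at the lower grid
#' edge the configuration is in the place-field regime and
#' \code{k_max = 0} is reported; when \eqn{\lambda_{max} \le 0} no
#' structure forms at all. With a learning rate \eqn{\eta}, patterns emerge
#' on the time scale \eqn{\tau_{str} = 1/(\eta \lambda_{max})}.
#'
#' @param cfg a [spectrumConfig()]
#' @param eta learning rate (for \code{tau_str}); optional
#' @param k_grid frequency grid (cycles/m), default 0.05..20 by 0.05
#' @return list with \code{k_max} (cycles/m; 0 in the place regime, NA when
#'   no mode grows), \code{lambda_max} (1/s), \code{tau_str} (s or NA),
#'   \code{regime} (\code{"grid"}, \code{"place"} or \code{"none"})
#' @export
criticalPoint <- function(cfg, eta = NULL,
                          k_grid = seq(0.05, 20, by = 0.05)) {
  lam <- eigenvalueSpectrum(cfg, k_grid)
  i <- which.max(lam)
  if (i == length(k_grid))
    warning("spectrum maximum at the upper grid edge; extend k_grid")
  lambda_max <- lam[i]
  if (i == 1) {
    k_max <- 0                       # supremum at k -> 0: place regime
  } else if (i == length(k_grid)) {
    k_max <- k_grid[i]
  } else {
    h <- k_grid[2] - k_grid[1]
    k_max <- refineParabolic(k_grid[i], h, lam[i - 1], lam[i], lam[i + 1])
    lambda_max <- max(eigenvalueSpectrum(cfg, k_max), lambda_max)
  }
  regime <- if (lambda_max <= 0) "none" else if (k_max == 0) "place" else "grid"
  tau_str <- if (!is.null(eta) && lambda_max > 0) 1 / (eta * lambda_max)
             else NA_real_
  list(k_max = if (regime == "none") NA_real_ else k_max,
       lambda_max = lambda_max, tau_str = tau_str, regime = regime)
}

#' Two-parameter sweep of the critical point
#'
#' Evaluates [criticalPoint()] over a grid of two kernel (or config)
#' parameters and classifies each cell as \code{"grid"} (\eqn{k_{max}>0}),
#' \code{"place"} (\eqn{k_{max}=0,\ \lambda_{max}>0}) or \code{"none"}
#' (\eqn{\lambda_{max} \le 0}). The classification is exhaustive and
#' mutually exclusive.
#'
#' @param make_cfg function of two scalars returning a [spectrumConfig()]
#' @param axis1,axis2 numeric vectors of parameter values
#' @param k_grid passed to [criticalPoint()]
#' @return list of matrices \code{k_max}, \code{lambda_max} and character
#'   matrix \code{regime}, with \code{axis1}, \code{axis2} attached
#' @export
sweepSpectrum <- function(make_cfg, axis1, axis2,
                          k_grid = seq(0.05, 20, by = 0.05)) {
  km <- lm_ <- matrix(NA_real_, length(axis1), length(axis2))
  rg <- matrix(NA_character_, length(axis1), length(axis2))
  for (i in seq_along(axis1)) for (j in seq_along(axis2)) {
    cp <- suppressWarnings(criticalPoint(make_cfg(axis1[i], axis2[j]),
                                         k_grid = k_grid))
    km[i, j] <- if (is.na(cp$k_max)) 0 else cp$k_max
    lm_[i, j] <- cp$lambda_max
    rg[i, j] <- cp$regime
  }
  list(k_max = km, lambda_max = lm_, regime = rg,
       axis1 = axis1, axis2 = axis2)
}

#' Attenuation factor for multi-field irregular inputs
#'
#' With \code{M} superimposed random fields per input, the expected power
#' spectrum of a tuning curve is attenuated by
#' \deqn{\Phi(M) = \frac{\pi}{3M}\left(\frac{4}{\pi} + \frac{1}{3M}\right)
#'   \approx \frac{4}{3M} \ (M > 3),}
#' derived from the Rayleigh distribution of the resultant of \code{M}
#' random phasors with U(0,1) amplitudes (numerator) and the Irwin--Hall
#' moments of their amplitude sum (denominator), for \eqn{|k| > 1/L}.
#' At \eqn{k = 0}, \eqn{\Phi = 1} (normalization is M-independent).
#'
#' @param M fields per neuron, \code{M >= 2}
#' @return list with \code{phi}, the coarse form \code{phi_coarse}
#'   \eqn{= 4/(3M)}, and \code{M}
#' @export
phiFactor <- function(M) {
  if (any(M < 2)) stop("the closed form is derived for M >= 2")
  list(phi = pi / (3 * M) * (4 / pi + 1 / (3 * M)),
       phi_coarse = 4 / (3 * M), M = M)
}

#' Monte-Carlo estimate of the attenuation factor
#'
#' Direct estimator of \eqn{\Phi = \langle \alpha^2/\beta^2 \rangle} with
#' \eqn{\alpha = |\sum_m A_m e^{2\pi j u_m}|}, \eqn{\beta = \sum_m A_m},
#' \eqn{A_m \sim U(0,1)}, \eqn{u_m \sim U(0,1)} (uniform phases, the
#' \eqn{|k| > 1/L} regime). Serves as the independent oracle for
#' [phiFactor()].
#'
#' @param M fields per neuron
#' @param n_draws Monte-Carlo sample size
#' @param seed optional seed
#' @return list with \code{phi_hat} and its standard error \code{se}
#' @export
phiMonteCarlo <- function(M, n_draws = 3600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(n_draws * M), n_draws, M)
  ph <- matrix(runif(n_draws * M), n_draws, M)
  alpha2 <- Mod(rowSums(A * exp(2i * pi * ph)))^2
  ratio <- alpha2 / rowSums(A)^2
  list(phi_hat = mean(ratio), se = sd(ratio) / sqrt(n_draws))
}

#' Expected eigenvalue spectrum for irregular inputs
#'
#' \deqn{\langle\lambda_{irr}(k)\rangle = \Phi(M)\, \rho W_{tot}
#'   \frac{4\pi^2}{L^2} \tilde G^2(k) \tilde K_{sp}(k) - a:}
#' the positive term of the regular spectrum scaled by \eqn{\Phi}, the
#' decay term unchanged. Since \eqn{\Phi} is k-independent for
#' \eqn{|k| > 1/L}, the critical frequency is the same as for regular
#' inputs for every \code{M}; only the growth rate (and hence
#' \eqn{\tau_{str}}) shrinks.
#'
#' @inheritParams eigenvalueSpectrum
#' @param M fields per neuron (\code{M >= 2}), or \code{phi} given directly
#' @param phi optional explicit attenuation factor (overrides \code{M})
#' @export
irregularSpectrum <- function(cfg, k, M = NULL, phi = NULL) {
  if (is.null(phi)) phi <- phiFactor(M)$phi
  phi * (eigenvalueSpectrum(cfg, k) + cfg$a) - cfg$a
}
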