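#' Temporal adaptation kernel
#'
#' Constructs the biphasic spike-rate adaptation kernel
#' \deqn{K(t) = \frac{1}{\tau_S} e^{-t/\tau_S} - \frac{\mu}{\tau_L} e^{-t/\tau_L}, \quad t \ge 0}
#' (and 0 for \eqn{t < 0}): a brief excitatory peak of time constant
#' \code{tau_s} followed by a slow hyperpolarizing tail of time constant
#' \code{tau_l}. The kernel integral is \eqn{1 - \mu}; \eqn{\mu > 1} gives a
#' net-inhibitory (negative-integral) kernel. Acting on the summed input
#' spike trains, the kernel performs a temporal band-pass filtering whose
#' resonance frequency sets, together with the running speed, the spatial
#' scale of emergent grid patterns.
#'
#' Internally a kernel is a sum of decaying exponentials
#' \eqn{K(t) = \sum_i c_i e^{-t/\tau_i}}; all transforms (Fourier, spatial
#' Hankel) are evaluated in closed form on this representation, so the
#' after-spike-potential equivalent kernel (also a two-exponential sum, see
#' [ahpEquivalentKernel()]) supports the identical contract.
#'
#' @param tau_s short (excitatory) time constant, seconds; \code{0 < tau_s < tau_l}
#' @param tau_l long (inhibitory) time constant, seconds
#' @param mu dimensionless scale of the inhibitory lobe, \code{mu > 0}
#' @return an object of class \code{adaptation_kernel} with elements
#'   \code{coef}, \code{tau} (exponential components), \code{tau_max}
#'   (\code{5 * tau_l}, beyond which \eqn{|K| < 0.01 |K(0)|}) and
#'   \code{tau_horizon} (quadrature horizon, \code{50 * tau_l}).
#' @examples
#' K <- adaptationKernel(0.1, 0.16, 1.06)
#' kernelValue(K, 0)        # 1/tau_s - mu/tau_l = 3.375 spikes/s
#' kernelIntegral(K)        # 1 - mu = -0.06
#' @export
adaptationKernel <- function(tau_s = 0.1, tau_l = 0.16, mu = 1.06) {
  if (!(tau_s > 0 && tau_l > tau_s))
    stop("need 0 < tau_s < tau_l")
  if (!(mu > 0)) stop("mu must be positive")
  newExpKernel(coef = c(1 / tau_s, -mu / tau_l),
               tau = c(tau_s, tau_l),
               params = list(tau_s = tau_s, tau_l = tau_l, mu = mu),
               kind = "adaptation")
}

newExpKernel <- function(coef, tau, params, kind) {
  structure(list(coef = coef, tau = tau, params = params, kind = kind,
                 tau_max = 5 * max(tau), tau_horizon = 50 * max(tau)),
            class = "adaptation_kernel")
}

#' After-spike-potential parameters
#'
#' Parameters of the alternative output model in which adaptation arises
#' from after-spike hyperpolarizing potentials (AHPs): an excitatory input
#' PSP kernel \eqn{K^{in}(t) = e^{-t/\tau_{in}}/\tau_{in}} and an inhibitory
#' output kernel \eqn{K^{out}(t) = -(\mu_{out}/\tau_{out}) e^{-t/\tau_{out}}}
#' fed back from the cell's own spikes.
#'
#' @param tau_in input PSP decay time constant (s); \code{tau_in < tau_out}
#' @param tau_out output AHP decay time constant (s)
#' @param mu_out magnitude of the (negative) output-kernel integral
#' @return object of class \code{ahp_params}
#' @export
ahpParams <- function(tau_in, tau_out, mu_out) {
  if (!(tau_in > 0 && tau_out > tau_in))
    stop("need 0 < tau_in < tau_out")
  if (!(mu_out > 0)) stop("mu_out must be positive")
  structure(list(tau_in = tau_in, tau_out = tau_out, mu_out = mu_out),
            class = "ahp_params")
}

#' Equivalent feed-forward kernel of the AHP model
#'
#' Averaging out the output-spike feedback, the AHP model reduces to the
#' feed-forward form with an equivalent kernel
#' \deqn{K^{eq}(t) = H\left[(1/\tau_{in} - 1/\tau_{out}) e^{-t/\tau_{in}}
#'   - (\mu_{out}/\tau_{out}) e^{-t (1+\mu_{out})/\tau_{out}}\right]}
#' with prefactor
#' \eqn{H = (1/\tau_{in}) / (1/\tau_{in} - (1+\mu_{out})/\tau_{out})}.
#' The result is again a two-exponential kernel and is returned as an
#' \code{adaptation_kernel}, so the whole spectral machinery
#' ([eigenvalueSpectrum()], [criticalPoint()], [sweepSpectrum()]) applies
#' unchanged. Its integral is \eqn{1/(1+\mu_{out})}, always positive.
#'
#' @param params an [ahpParams()] object
#' @return an \code{adaptation_kernel} of kind \code{"ahp_equivalent"}
#' @export
ahpEquivalentKernel <- function(params) {
  stopifnot(inherits(params, "ahp_params"))
  ti <- params$tau_in; to <- params$tau_out; mo <- params$mu_out
  denom <- 1 / ti - (1 + mo) / to
  if (abs(denom) < 1e-12)
    stop("degenerate AHP parameters: 1/tau_in == (1 + mu_out)/tau_out")
  H <- (1 / ti) / denom
  newExpKernel(coef = c(H * (1 / ti - 1 / to), -H * mo / to),
               tau = c(ti, to / (1 + mo)),
               params = c(params, list(H = H)),
               kind = "ahp_equivalent")
}

#' @export
print.adaptation_kernel <- function(x, ...) {
  cat(sprintf("<%s kernel>  K(0) = %.4g 1/s, integral = %.4g, tau_max = %.3g s\n",
              x$kind, kernelValue(x, 0), kernelIntegral(x), x$tau_max))
  invisible(x)
}

#' Evaluate a temporal kernel
#'
#' @param kernel an \code{adaptation_kernel}
#' @param t times (s); negative times return exactly 0 (causality)
#' @return kernel amplitude (1/s)
#' @export
kernelValue <- function(kernel, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (any(pos)) {
    tp <- t[pos]
    acc <- 0
    for (i in seq_along(kernel$coef))
      acc <- acc + kernel$coef[i] * exp(-tp / kernel$tau[i])
    out[pos] <- acc
  }
  out
}

#' Kernel integral (closed form)
#'
#' \eqn{\int_0^\infty K = \sum_i c_i \tau_i}; equals \eqn{1-\mu} for the
#' adaptation kernel and \eqn{1/(1+\mu_{out})} for the AHP equivalent.
#' @inheritParams kernelValue
#' @export
kernelIntegral <- function(kernel) sum(kernel$coef * kernel$tau)

#' Frequency response of a temporal kernel
#'
#' Fourier transform of the kernel at ordinary frequency \code{f} (cycles/s),
#' \eqn{\hat K(f) = \sum_i c_i \tau_i / (1 + 2\pi j f \tau_i)}. For the
#' adaptation kernel this is
#' \eqn{1/(1 + 2\pi j f \tau_S) - \mu/(1 + 2\pi j f \tau_L)}: a band-pass
#' response with DC gain \eqn{1-\mu}.
#'
#' @inheritParams kernelValue
#' @param f frequency, cycles per second
#' @return complex gain
#' @export
kernelFrequencyResponse <- function(kernel, f) {
  acc <- 0 + 0i
  for (i in seq_along(kernel$coef))
    acc <- acc + kernel$coef[i] * kernel$tau[i] /
      (1 + 2i * pi * f * kernel$tau[i])
  acc
}

#' Resonance frequency of a kernel
#'
#' Frequency maximizing \eqn{|\hat K(f)|}, found on a dense grid with local
#' parabolic refinement. The default adaptation kernel resonates at
#' 1.23 cycles/s.
#'
#' @inheritParams kernelValue
#' @param f_max upper end of the scanned band (cycles/s)
#' @param df grid step (cycles/s)
#' @export
resonanceFrequency <- function(kernel, f_max = 10, df = 1e-3) {
  f <- seq(0, f_max, by = df)
  g <- Mod(kernelFrequencyResponse(kernel, f))
  i <- which.max(g)
  if (i == 1 || i == length(f)) return(f[i])
  refineParabolic(f[i], df, g[i - 1], g[i], g[i + 1])
}

# vertex of the parabola through three equally spaced samples
refineParabolic <- function(x0, h, ym, y0, yp) {
  d <- ym - 2 * y0 + yp
  if (d == 0) return(x0)
  x0 + 0.5 * h * (ym - yp) / d
}

#' Equivalent adaptation kernel in space
#'
#' When the animal runs at constant speed \code{v}, the temporal kernel acts
#' on space as the circularly symmetric kernel
#' \eqn{K_{sp}(r) = K(r/v) / (r v)}. The pointwise singularity at
#' \eqn{r = 0} is integrable (its 2D integral is \eqn{2\pi(1-\mu)}).
#'
#' @inheritParams kernelValue
#' @param v running speed (m/s), positive
#' @param r distance (m), strictly positive
#' @return amplitude (1/m^2 scaled by the kernel units)
#' @export
spatialKernelValue <- function(kernel, v, r) {
  if (!(v > 0)) stop("v must be positive")
  if (any(r <= 0)) stop("K_sp is singular at r = 0; r must be > 0")
  kernelValue(kernel, r / v) / (r * v)
}

#' Hankel transform of the spatial kernel (closed form)
#'
#' Zeroth-order Hankel transform
#' \eqn{\tilde K_{sp}(k) = \int_0^\infty K(\tau) J_0(2\pi k v \tau) d\tau},
#' with \code{k} in cycles per meter (the Bessel argument carries the
#' \eqn{2\pi}). For an exponential component \eqn{c\,e^{-\tau/\tau_i}} the
#' integral is \eqn{c / \sqrt{\tau_i^{-2} + (2\pi k v)^2}}, giving the
#' Lorentzian-type expression
#' \deqn{\tilde K_{sp}(k) = \frac{1}{\tau_S v}\left[(2\pi k)^2 +
#'   (\tau_S v)^{-2}\right]^{-1/2} - \frac{\mu}{\tau_L v}\left[(2\pi k)^2 +
#'   (\tau_L v)^{-2}\right]^{-1/2}.}
#' At \eqn{k = 0} this reduces to the kernel integral.
#'
#' @inheritParams spatialKernelValue
#' @param k spatial frequency, cycles per meter, \code{k >= 0}
#' @return transform value (s)
#' @export
spatialKernelHankel <- function(kernel, v, k) {
  if (any(k < 0)) stop("k must be non-negative")
  w <- 2 * pi * k * v
  acc <- 0
  for (i in seq_along(kernel$coef))
    acc <- acc + kernel$coef[i] / sqrt(1 / kernel$tau[i]^2 + w^2)
  acc
}

# Gauss-Legendre quadrature rule over (0, tau_horizon], refined on
# (0, tau_max] where the kernel is large; returns list(x, w).
# The long tail matters: it is pointwise small but carries a
# non-negligible share of the (small) kernel integral.
kernelQuadrature <- function(kernel, n_core = 200, n_tail = 120) {
  g1 <- pracma::gaussLegendre(n_core, 0, kernel$tau_max)
  g2 <- pracma::gaussLegendre(n_tail, kernel$tau_max, kernel$tau_horizon)
  list(x = c(g1$x, g2$x), w = c(g1$w, g2$w))
}
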