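#' STDP plasticity parameters
#'
#' The learning rule combines (i) a symmetric Hebbian window applied to
#' every pre/post spike pair, \eqn{W(\Delta t) = \frac{W_{tot}}{2\tau_W}
#' e^{-|\Delta t|/\tau_W}}, and (ii) a local normalization term
#' \eqn{\Delta w_i = \eta(\beta - \alpha w_i)} applied at every presynaptic
#' spike, which stabilizes the mean weight. Weights are hard-bounded at 0.
#'
#' @param eta learning rate (dimensionless, small)
#' @param tau_w window time constant (s)
#' @param w_tot window integral (s)
#' @param alpha multiplicative decay coefficient (> 0)
#' @param beta additive coefficient (may be negative)
#' @export
plasticityParams <- function(eta = 2e-5, tau_w = 0.05, w_tot = 1,
                             alpha = 3.56, beta = -8.78) {
  if (!(eta > 0 && tau_w > 0 && alpha > 0)) stop("need eta, tau_w, alpha > 0")
  structure(list(eta = eta, tau_w = tau_w, w_tot = w_tot,
                 alpha = alpha, beta = beta),
            class = "plasticity_params")
}

#' Output-neuron parameters
#'
#' @param r0 baseline output rate (1/s)
#' @param dt_neural integration step (s), default 1 ms
#' @export
neuronParams <- function(r0 = 10, dt_neural = 1e-3) {
  if (r0 < 0 || dt_neural <= 0) stop("need r0 >= 0 and dt_neural > 0")
  structure(list(r0 = r0, dt_neural = dt_neural), class = "neuron_params")
}

#' STDP learning window
#'
#' \eqn{W(\Delta t) = \frac{W_{tot}}{2\tau_W} e^{-|\Delta t|/\tau_W}}:
#' symmetric, with total integral \code{w_tot}.
#'
#' @param plasticity a [plasticityParams()] object
#' @param dt pre-minus-post spike time differences (s)
#' @export
stdpWindow <- function(plasticity, dt) {
  plasticity$w_tot / (2 * plasticity$tau_w) * exp(-abs(dt) / plasticity$tau_w)
}

#' Run the stochastic spiking simulation
#'
#' The full model: input spike trains are inhomogeneous Poisson processes
#' with rates set by the input tuning curves along the trajectory
#' (zero-order hold between walk updates); the output rate is
#' \eqn{r^{out}(t) = r_0 + \int K(\tau) \sum_i w_i S^{in}_i(t-\tau) d\tau}
#' (rectified at 0 before the Poisson draw); output spikes are Poisson at
#' \eqn{r^{out}}; and every spike triggers the STDP updates of
#' [plasticityParams()]. The adaptation integral is maintained by exact
#' exponential traces, and all-to-all spike pairing by exponential pre/post
#' traces (exact for the exponential window).
#'
#' @param ensemble input ensemble ([makeRegularEnsemble()] /
#'   [makeIrregularEnsemble()])
#' @param traj trajectory from [simulateWalk()]; must cover \code{duration}
#' @param kernel adaptation kernel
#' @param neuron [neuronParams()]
#' @param plasticity [plasticityParams()]; pass \code{eta = 0} via
#'   \code{freeze = TRUE} to freeze weights
#' @param w_init initial weight vector (length N) or \code{NULL} to draw
#'   Normal(\code{w_init_mean}, \code{w_init_sd}) clamped at 0
#' @param checkpoints times (s) at which weights are recorded; defaults to
#'   the end of the run
#' @param duration simulated time (s); defaults to the trajectory length
#' @param w_init_mean,w_init_sd initial-weight distribution (defaults
#'   5e-3 and 1e-4)
#' @param freeze logical; \code{TRUE} disables plasticity
#' @param seed optional integer seed for the spiking randomness
#' @param record_spikes keep output spike times?
#' @return list with \code{w_hist} (checkpoints x N), \code{checkpoints},
#'   \code{w_init}, spike counts, and optionally \code{out_spike_times}
#' @export
simulateSpiking <- function(ensemble, traj, kernel = adaptationKernel(),
                            neuron = neuronParams(),
                            plasticity = plasticityParams(),
                            w_init = NULL, checkpoints = NULL,
                            duration = NULL,
                            w_init_mean = 5e-3, w_init_sd = 1e-4,
                            freeze = FALSE, seed = NULL,
                            record_spikes = FALSE) {
  dt_walk <- attr(traj, "dt_walk")
  dt <- neuron$dt_neural
  hold <- round(dt_walk / dt)
  if (abs(hold * dt - dt_walk) > 1e-9)
    stop("dt_walk must be an integer multiple of dt_neural")
  if (is.null(duration)) duration <- nrow(traj) * dt_walk
  n_upd <- floor(duration / dt_walk)
  if (n_upd > nrow(traj)) stop("trajectory shorter than duration")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(w_init))
    w_init <- pmax(rnorm(ensemble$N, w_init_mean, w_init_sd), 0)
  if (length(w_init) != ensemble$N)
    stop("w_init length does not match ensemble size N")
  rates <- ensembleRates(ensemble, cbind(traj$x[seq_len(n_upd)],
                                         traj$y[seq_len(n_upd)]))
  if (max(rates) * dt > 0.2)
    warning("rate * dt_neural exceeds 0.2; Bernoulli approximation is poor")
  if (is.null(checkpoints)) checkpoints <- duration
  cp_steps <- as.integer(round(sort(checkpoints) / dt))
  cp_steps <- pmin(pmax(cp_steps, 1L), n_upd * hold)
  res <- .spikingCore(rates, w_init, dt, hold,
                      kernel$params$tau_s, kernel$params$tau_l,
                      kernel$params$mu,
                      neuron$r0,
                      if (freeze) 0 else plasticity$eta,
                      plasticity$tau_w, plasticity$w_tot,
                      plasticity$alpha, plasticity$beta,
                      cp_steps, record_spikes)
  list(w_hist = res$w_hist, checkpoints = cp_steps * dt,
       w_init = w_init,
       n_out_spikes = res$n_out_spikes, n_in_spikes = res$n_in_spikes,
       out_spike_times = if (record_spikes) res$out_spike_times else NULL,
       duration = n_upd * dt_walk)
}
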