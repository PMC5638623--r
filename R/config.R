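#' Published simulation parameter presets
#'
#' The six default parameter columns used for the numerical experiments:
#' one spiking configuration on the 1 m arena (\code{"regular-spiking"}),
#' four averaged-dynamics configurations on the 2 m arena spanning two
#' adaptation time constants and two field widths
#' (\code{"scale-tl"}, \code{"scale-tr"}, \code{"scale-bl"},
#' \code{"scale-br"}), and the multi-field irregular-input configuration
#' (\code{"irregular"}). Each preset bundles the neural, exploration,
#' input-tuning and plasticity parameters; \code{a} and \code{b} are given
#' directly where the original runs did not use the spiking STDP rule.
#'
#' @param name preset name; with no argument, all presets are returned
#' @return a list (or named list of lists) of parameter blocks
#' @export
parameterPreset <- function(name = NULL) {
  base <- list(tau_s = 0.1, mu = 1.06, v = 0.25, sigma_theta = 0.7,
               w_tot = 1, dt_euler = 50, dt_walk = 0.01, dt_neural = 1e-3)
  p <- list(
    `regular-spiking` = c(base, list(
      N = 900, r0 = 10, tau_l = 0.16, L = 1, r_av = 0.4, sigma = 0.0625,
      M = NA, eta = 2e-5, tau_w = 0.05, alpha = 3.56, beta = -8.78,
      a = NA, b = NA, t_end = 1e6)),
    `scale-tl` = c(base, list(
      N = 3600, r0 = 4, tau_l = 0.16, L = 2, r_av = 0.21, sigma = 0.045,
      M = NA, eta = 5e-5, tau_w = NA, alpha = NA, beta = NA,
      a = 4, b = 0.69, t_end = 1e6)),
    `scale-tr` = c(base, list(
      N = 3600, r0 = 4, tau_l = 0.35, L = 2, r_av = 0.085, sigma = 0.045,
      M = NA, eta = 5e-5, tau_w = NA, alpha = NA, beta = NA,
      a = 4, b = 0.28, t_end = 1e6)),
    `scale-bl` = c(base, list(
      N = 3600, r0 = 4, tau_l = 0.16, L = 2, r_av = 0.3, sigma = 0.0625,
      M = NA, eta = 5e-5, tau_w = NA, alpha = NA, beta = NA,
      a = 4, b = 1.23, t_end = 1e6)),
    `scale-br` = c(base, list(
      N = 3600, r0 = 4, tau_l = 0.35, L = 2, r_av = 0.1, sigma = 0.0625,
      M = NA, eta = 5e-5, tau_w = NA, alpha = NA, beta = NA,
      a = 4, b = 0.31, t_end = 1e6)),
    irregular = c(base, list(
      N = 3600, r0 = 4, tau_l = 0.16, L = 1, r_av = 0.8, sigma = 0.0625,
      M = 10, eta = 5e-5, tau_w = NA, alpha = NA, beta = NA,
      a = 2.5, b = 2.8, t_end = 1e6))
  )
  if (is.null(name)) return(p)
  if (!name %in% names(p)) stop("unknown preset: ", name)
  p[[name]]
}

presetKernel <- function(p) adaptationKernel(p$tau_s, p$tau_l, p$mu)
presetSpec <- function(p) gaussianFieldSpec(p$sigma, p$r_av, p$L)

presetAB <- function(p) {
  if (!is.na(p$a)) return(list(a = p$a, b = p$b))
  ab <- deriveAB(plasticityParams(p$eta, p$tau_w, p$w_tot, p$alpha, p$beta),
                 presetKernel(p), neuronParams(p$r0), p$r_av)
  list(a = ab$a, b = ab$b)
}

#' Derived quantities for a parameter preset
#'
#' Recomputes the derived rows of the default-parameter table: the
#' averaged-dynamics rates \code{a}, \code{b} (from the STDP parameters
#' where available), the spectral peak (\code{k_max},
#' \code{lambda_max}, with the \eqn{\Phi(M)} attenuation for the irregular
#' preset), the normalization level \code{w_av_inf} and time scale
#' \code{tau_av}, and the structure-formation time \code{tau_str}.
#'
#' \code{c_av_method = "continuum"} uses the \eqn{k = 0} limit
#' \eqn{N C_{av} = \rho \hat C(0)} (\eqn{\Phi(0) = 1}, so the same formula
#' holds for irregular inputs); \code{"discrete"} builds the discrete
#' correlation matrix and averages it (slower; regular ensembles only).
#'
#' @param preset preset name or parameter list
#' @param c_av_method \code{"continuum"} or \code{"discrete"}
#' @return one-row data.frame of derived quantities
#' @export
derivedQuantities <- function(preset, c_av_method = "continuum") {
  p <- if (is.character(preset)) parameterPreset(preset) else preset
  ab <- presetAB(p)
  kern <- presetKernel(p)
  spec <- presetSpec(p)
  rho <- p$N / p$L^2
  cfg <- spectrumConfig(rho, spec, kern, p$v, p$w_tot, ab$a)
  cp <- if (!is.na(p$M))
    criticalPointIrregular(cfg, p$M, p$eta) else criticalPoint(cfg, p$eta)
  n_c_av <- switch(c_av_method,
    continuum = rho * p$w_tot * 4 * pi^2 / p$L^2 *
      gaussianHankel(spec, 0)^2 * kernelIntegral(kern),
    discrete = {
      ens <- makeRegularEnsemble(p$N, spec)
      p$N * mean(correlationMatrix(ens, kern, p$v, p$w_tot,
                                   method = "radial")$matrix)
    },
    stop("unknown c_av_method"))
  denom <- ab$a - n_c_av
  data.frame(a = ab$a, b = ab$b,
             k_max = cp$k_max, lambda_max = cp$lambda_max,
             w_av_inf = ab$b / denom, tau_av = 1 / (p$eta * denom),
             tau_str = cp$tau_str)
}

# critical point of the Phi-attenuated irregular spectrum
criticalPointIrregular <- function(cfg, M, eta = NULL,
                                   k_grid = seq(0.05, 20, by = 0.05)) {
  phi <- phiFactor(M)$phi
  lam <- irregularSpectrum(cfg, k_grid, phi = phi)
  i <- which.max(lam)
  h <- k_grid[2] - k_grid[1]
  k_max <- if (i %in% c(1L, length(k_grid))) k_grid[i]
           else refineParabolic(k_grid[i], h, lam[i - 1], lam[i], lam[i + 1])
  lambda_max <- max(lam)
  list(k_max = k_max, lambda_max = lambda_max,
       tau_str = if (!is.null(eta) && lambda_max > 0)
         1 / (eta * lambda_max) else NA_real_)
}

#' Validate a run configuration
#'
#' Checks module invariants and cross-module consistency; returns a
#' character vector of violations (empty when the configuration is sound).
#'
#' @param p parameter list (as from [parameterPreset()] or
#'   [readRunConfig()])
#' @export
validateConfig <- function(p) {
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  chk(!(p$tau_s > 0 && p$tau_l > p$tau_s), "need 0 < tau_s < tau_l")
  chk(!(p$mu > 0), "mu must be positive")
  chk(!(p$L > 0), "L must be positive")
  chk(!(p$v >= 0), "v must be non-negative")
  chk(!(p$sigma > 0), "sigma must be positive")
  chk(!(p$r_av > 0), "r_av must be positive")
  chk(is.na(p$M) && round(sqrt(p$N))^2 != p$N,
      "regular ensembles need N to be a perfect square")
  chk(!is.null(p$sigma) && !is.null(p$L) && p$sigma > p$L / 4,
      "sigma > L/4: periodic Gaussian truncation inaccurate")
  ab <- tryCatch(presetAB(p), error = function(e) NULL)
  if (is.null(ab)) {
    v <- c(v, "cannot determine a, b (missing plasticity parameters)")
  } else if (!is.na(p$eta) && !is.null(p$dt_euler)) {
    cfg <- spectrumConfig(p$N / p$L^2, presetSpec(p), presetKernel(p),
                          p$v, p$w_tot, ab$a)
    lam <- suppressWarnings(criticalPoint(cfg)$lambda_max)
    chk(p$eta * p$dt_euler * max(abs(lam), abs(ab$a)) > 0.1,
        "dt_euler * eta * |lambda_max| > 0.1: explicit Euler may be unstable")
  }
  v
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with parameter keys as in [parameterPreset()],
#'   optionally starting from a \code{preset:} name
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` key as boolean FALSE; the only such key in
  # the schema is the input count, so map it back
  names(y)[names(y) == "FALSE"] <- "N"
  p <- if (!is.null(y$preset)) parameterPreset(y$preset)
       else parameterPreset("regular-spiking")
  for (k in setdiff(names(y), "preset")) p[[k]] <- y[[k]]
  p
}

# stable rolling hash of a config (for provenance records)
configHash <- function(p) {
  s <- jsonlite::toJSON(p[order(names(p))], auto_unbox = TRUE, digits = 12)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

deriveSeed <- function(master, stream) {
  (as.integer(master) * 7919 + stream) %% 2147483647L
}

#' Run a scripted experiment
#'
#' End-to-end pipelines over the module stack, driven by a parameter list
#' and a master seed (per-component streams are derived deterministically).
#' Artifacts (CSV curves/maps, JSON metadata including the config hash)
#' are written under \code{out_dir} when given.
#'
#' @param p parameter list ([parameterPreset()] / [readRunConfig()])
#' @param experiment one of \code{"derived"} (derived-quantity table),
#'   \code{"spectrum"} (eigenvalue curve + critical point),
#'   \code{"averaged"} (input ensemble, averaged weight dynamics, grid
#'   metrics), \code{"spiking"} (trajectory, spiking simulation, grid
#'   metrics of the final weight map)
#' @param seed master seed
#' @param out_dir optional output directory
#' @param scale \code{"desk"} (shortened duration \code{t_end/5}, smaller
#'   grids) or \code{"full"} (the published durations)
#' @return list with the experiment results and a \code{record} (config
#'   hash, seed, scale, elapsed time)
#' @export
runExperiment <- function(p, experiment = c("derived", "spectrum",
                                            "averaged", "spiking"),
                          seed = 1, out_dir = NULL,
                          scale = c("desk", "full")) {
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  viol <- validateConfig(p)
  if (length(viol))
    stop("invalid config: ", paste(viol, collapse = "; "))
  t0 <- proc.time()[3]
  ab <- presetAB(p)
  kern <- presetKernel(p)
  spec <- presetSpec(p)
  t_end <- if (scale == "desk") p$t_end / 5 else p$t_end
  res <- switch(experiment,
    derived = derivedQuantities(p),
    spectrum = {
      cfg <- spectrumConfig(p$N / p$L^2, spec, kern, p$v, p$w_tot, ab$a)
      k <- seq(0.05, 10, by = 0.05)
      list(k = k, lambda = eigenvalueSpectrum(cfg, k),
           critical = criticalPoint(cfg, p$eta))
    },
    averaged = {
      set.seed(deriveSeed(seed, 1L))
      if (is.na(p$M)) {
        ens <- makeRegularEnsemble(p$N, spec)
        model <- correlationMatrix(ens, kern, p$v, p$w_tot, method = "radial")
      } else {
        ens <- makeIrregularEnsemble(p$N, p$M, spec,
                                     seed = deriveSeed(seed, 2L))
        model <- modeOperator(ens, kern, p$v, p$w_tot)
      }
      set.seed(deriveSeed(seed, 3L))
      w0 <- pmax(rnorm(p$N, 5e-3, 1e-3), 0)
      sol <- integrateAveraged(model, ab$a, ab$b, p$eta, w0, t_end,
                               p$dt_euler)
      map <- if (is.na(p$M)) weightMap(sol$w, p$L)
             else outputRateMap(ens, sol$w, kern, p$v, p$r0,
                                n_bins = if (scale == "desk") 60 else 100)
      g <- gridness(map)
      list(w = sol$w, map = map, metrics = c(g, list(
        orientation = tryCatch(gridOrientation(map),
                               error = function(e) NA_real_))))
    },
    spiking = {
      traj <- simulateWalk(t_end, p$v, p$sigma_theta, p$dt_walk, p$L,
                           seed = deriveSeed(seed, 1L))
      ens <- makeRegularEnsemble(p$N, spec)
      sim <- simulateSpiking(ens, traj, kern,
                             neuronParams(p$r0, p$dt_neural),
                             plasticityParams(p$eta, p$tau_w, p$w_tot,
                                              p$alpha, p$beta),
                             seed = deriveSeed(seed, 4L))
      map <- weightMap(sim$w_hist[nrow(sim$w_hist), ], p$L)
      list(sim = sim, map = map, metrics = gridness(map))
    })
  record <- list(config_hash = configHash(p), experiment = experiment,
                 seed = seed, scale = scale,
                 elapsed_s = unname(proc.time()[3] - t0))
  if (!is.null(out_dir)) writeArtifacts(res, record, p, out_dir, experiment)
  list(result = res, record = record)
}

writeArtifacts <- function(res, record, p, out_dir, experiment) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(record = record, params = p),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  if (experiment == "derived")
    utils::write.csv(res, file.path(out_dir, "derived.csv"),
                     row.names = FALSE)
  if (experiment == "spectrum")
    utils::write.csv(data.frame(k = res$k, lambda = res$lambda),
                     file.path(out_dir, "spectrum.csv"), row.names = FALSE)
  if (experiment %in% c("averaged", "spiking")) {
    utils::write.csv(res$map$values, file.path(out_dir, "map.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = 12)
  }
  invisible(NULL)
}

#' Export a kernel curve as CSV
#'
#' @param kernel adaptation kernel
#' @param path output file
#' @param t times (s)
#' @export
writeKernelCurve <- function(kernel, path,
                             t = seq(0, kernel$tau_max, length.out = 401)) {
  utils::write.csv(data.frame(t = t, K = kernelValue(kernel, t)), path,
                   row.names = FALSE)
}

#' Export a trajectory as CSV
#'
#' @param traj a [simulateWalk()] trajectory
#' @param path output file
#' @export
writeTrajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
}
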