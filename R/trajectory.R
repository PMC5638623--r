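#' Correlated random walk on a periodic arena
#'
#' Simulates the virtual rat's exploration: the heading performs a Brownian
#' motion (\eqn{\theta_t = \sigma_\theta W_t}, Euler--Maruyama with step
#' \code{dt_walk}) and the position advances along the current heading at
#' speed \code{v}, wrapped periodically on the square arena \eqn{[0,L)^2}.
#' With \code{speed_ou} given, the speed itself follows an
#' Ornstein--Uhlenbeck process
#' \eqn{dv = \theta_v(\bar v - v)\,dt + \sigma_v\,dW}, reflected at 0 to
#' keep it physical (the stationary mean is \eqn{\bar v} and the stationary
#' s.d. \eqn{\sigma_v/\sqrt{2\theta_v}}).
#'
#' @param duration total time (s), at least one step
#' @param v constant running speed (m/s); also the OU long-term mean when
#'   \code{speed_ou} is supplied
#' @param sigma_theta heading diffusion (rad s^-1/2); 0 gives a straight run
#' @param dt_walk update step (s), default 10 ms
#' @param L arena side length (m)
#' @param speed_ou \code{NULL}, or \code{list(sigma_v =, theta_v =)} for the
#'   OU speed process (volatility in m s^-1.5, mean reversion in 1/s)
#' @param seed optional integer; when given, sets the RNG seed locally
#' @param x0 starting position, defaults to the arena center
#' @return a \code{trajectory}: data.frame with columns \code{t, x, y,
#'   heading, speed} and attributes \code{L, dt_walk}
#' @examples
#' tr <- simulateWalk(10, v = 0.25, sigma_theta = 0.7, seed = 1)
#' range(tr$x)  # inside [0, 1)
#' @export
simulateWalk <- function(duration, v = 0.25, sigma_theta = 0.7,
                         dt_walk = 0.01, L = 1, speed_ou = NULL,
                         seed = NULL, x0 = c(L / 2, L / 2)) {
  if (!(dt_walk > 0) || duration < dt_walk) stop("duration < dt_walk")
  if (v < 0 || L <= 0) stop("need v >= 0 and L > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt_walk)
  dth <- rnorm(n, 0, sigma_theta * sqrt(dt_walk))
  heading <- cumsum(c(runif(1, 0, 2 * pi), dth))[-(n + 1)]
  if (is.null(speed_ou)) {
    speed <- rep(v, n)
  } else {
    th_v <- speed_ou$theta_v; s_v <- speed_ou$sigma_v
    if (!(th_v > 0) || s_v < 0) stop("need theta_v > 0, sigma_v >= 0")
    speed <- numeric(n)
    s <- v
    dw <- rnorm(n, 0, sqrt(dt_walk))
    for (i in seq_len(n)) {
      s <- s + th_v * (v - s) * dt_walk + s_v * dw[i]
      s <- abs(s)                       # reflect at 0
      speed[i] <- s
    }
  }
  dx <- speed * cos(heading) * dt_walk
  dy <- speed * sin(heading) * dt_walk
  x <- (x0[1] + cumsum(dx)) %% L
  y <- (x0[2] + cumsum(dy)) %% L
  out <- data.frame(t = seq_len(n) * dt_walk, x = x, y = y,
                    heading = heading, speed = speed)
  attr(out, "L") <- L
  attr(out, "dt_walk") <- dt_walk
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Occupancy histogram of a trajectory
#'
#' Normalized 2D histogram of visited positions; for an ergodic walk it
#' converges to the uniform density \eqn{1/n_{bins}^2} per bin, which is the
#' assumption underlying the averaged weight dynamics.
#'
#' @param traj a [simulateWalk()] trajectory
#' @param n_bins bins per axis
#' @return an \code{n_bins x n_bins} matrix summing to 1 (row index = x bin,
#'   column index = y bin, origin at the lower-left)
#' @export
occupancyMap <- function(traj, n_bins) {
  if (nrow(traj) == 0) stop("empty trajectory")
  if (n_bins < 1) stop("n_bins must be >= 1")
  L <- attr(traj, "L")
  ix <- pmin(floor(traj$x / L * n_bins), n_bins - 1) + 1
  iy <- pmin(floor(traj$y / L * n_bins), n_bins - 1) + 1
  h <- matrix(0, n_bins, n_bins)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  h / sum(h)
}

# minimal-image displacement on the torus [0,L)^2
torusDelta <- function(d, L) {
  d <- (d + L / 2) %% L - L / 2
  d
}

#' Minimal-image distance on the torus
#'
#' @param x1,x2 2-column matrices (or length-2 vectors) of positions
#' @param L arena side (m)
#' @export
torusDistance <- function(x1, x2, L) {
  x1 <- rbind(x1); x2 <- rbind(x2)
  dx <- torusDelta(x1[, 1] - x2[, 1], L)
  dy <- torusDelta(x1[, 2] - x2[, 2], L)
  sqrt(dx^2 + dy^2)
}
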