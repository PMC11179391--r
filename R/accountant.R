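# Privacy accounting for the Poisson-subsampled Gaussian mechanism under the
# add-remove neighbourhood relation. The primary accountant discretizes the
# privacy loss distribution (PLD) of a single step in both adjacency
# directions, composes T iterations by FFT convolution, and reads off the
# hockey-stick divergence delta(eps); eps(delta) follows by bisection. An
# integer-order Renyi-DP composition bound serves as an independent upper
# bound for cross-checking.

# Per-step privacy loss densities. With noise multiplier sigma (sensitivity
# normalised to 1) and subsampling rate q, the two neighbouring output
# densities are P = (1-q) N(0, s^2) + q N(1, s^2) versus Q = N(0, s^2).
# The loss L(x) = log(P(x)/Q(x)) = log(1 - q + q e^{(x - 1/2)/s^2}) is
# strictly increasing with inverse x(l) = s^2 log((e^l - (1-q))/q) + 1/2.

pld_grid <- function(sigma, q, iterations, delta, grid_points = 2^18) {
  # Per-step loss moments under both directions, by quadrature in x-space,
  # to size the grid so the T-fold support fits without wrap-around.
  xs <- seq(-14 * sigma, 1 + 14 * sigma, length.out = 40001)
  dx <- xs[2] - xs[1]
  f0 <- stats::dnorm(xs, 0, sigma)
  f1 <- stats::dnorm(xs, 1, sigma)
  pmix <- (1 - q) * f0 + q * f1
  u <- (xs - 0.5) / sigma^2
  loss <- if (q == 1) u else log1p(q * expm1(u))
  big <- u > 30  # log(1 - q + q e^u) ~ log(q) + u, overflow-safe
  loss[big] <- log(q) + u[big]
  m_p <- sum(loss * pmix) * dx
  s_p <- sqrt(max(sum((loss - m_p)^2 * pmix) * dx, 1e-12))
  m_q <- sum(-loss * f0) * dx
  s_q <- sqrt(max(sum((-loss - m_q)^2 * f0) * dx, 1e-12))
  L <- max(abs(m_p) * iterations + 30 * s_p * sqrt(iterations),
           abs(m_q) * iterations + 30 * s_q * sqrt(iterations),
           8) + 4
  n <- grid_points
  dt <- 2 * L / n
  s_grid <- -L + (seq_len(n) - 0.5) * dt
  list(L = L, n = n, dt = dt, s = s_grid)
}

# Discretized per-step PLD masses on the grid, for one direction.
#  direction "remove": loss log(P/Q), x ~ P;  "add": loss log(Q/P), x ~ Q.
# Each grid cell receives the exact probability of the loss falling inside it
# (CDF differences at the cell edges), so arbitrarily narrow loss
# distributions are captured without quadrature loss.
pld_step_mass <- function(grid, sigma, q, direction) {
  lo <- if (q < 1) log1p(-q) else -Inf
  # inverse loss x(s), monotone increasing; -Inf below the support
  x_of <- function(s) {
    x <- rep(-Inf, length(s))
    ok <- s > lo & is.finite(s)
    sv <- s[ok]
    x[ok] <- if (q == 1) {
      sigma^2 * sv + 0.5
    } else {
      sigma^2 * (sv + log1p(-(1 - q) * exp(-sv)) - log(q)) + 0.5
    }
    x[is.finite(s) & !ok] <- -Inf
    x[s == Inf] <- Inf
    x
  }
  edges <- -grid$L + (0:grid$n) * grid$dt
  if (direction == "remove") {
    xe <- x_of(edges)
    Fe <- (1 - q) * stats::pnorm(xe, 0, sigma) + q * stats::pnorm(xe, 1, sigma)
    mass <- diff(Fe)
  } else {
    xe <- x_of(-edges)
    Fe <- stats::pnorm(xe, 0, sigma)
    mass <- Fe[-length(Fe)] - Fe[-1]
  }
  mass[mass < 0] <- 0
  tot <- sum(mass)
  if (tot < 1 - 1e-6) {
    stop("PLD grid truncates too much probability mass (", format(1 - tot),
         "); increase the grid range")
  }
  mass / tot
}

# T-fold composition by FFT; returns masses aligned to values `vals`.
pld_compose <- function(grid, mass, iterations) {
  if (iterations == 1) {
    return(list(vals = grid$s, mass = mass))
  }
  f <- stats::fft(mass)
  conv <- Re(stats::fft(f^iterations, inverse = TRUE)) / grid$n
  conv[conv < 0] <- 0
  # index m holds the sum-value congruent to (m-1)*dt - T*(L - dt/2) mod 2L,
  # mapped back into [-L, L)
  offset <- -iterations * (grid$L - grid$dt / 2)
  vals <- ((seq_len(grid$n) - 1) * grid$dt + offset + grid$L) %% (2 * grid$L) - grid$L
  list(vals = vals, mass = conv)
}

pld_delta_fun <- function(composed) {
  vals <- composed$vals
  mass <- composed$mass
  function(eps) {
    sel <- vals > eps
    sum((1 - exp(eps - vals[sel])) * mass[sel])
  }
}

#' Total privacy cost of repeated subsampled Gaussian steps
#'
#' Computes the smallest \eqn{\varepsilon} such that `iterations` rounds of
#' the Poisson-subsampled Gaussian mechanism (subsampling rate `q`, noise
#' multiplier `sigma`) satisfy \eqn{(\varepsilon, \delta)}-differential
#' privacy under the add-remove neighbourhood relation. The computation uses
#' a numerical privacy-loss-distribution accountant: the one-step loss
#' distribution is discretized on a fine grid in both adjacency directions,
#' composed over iterations by FFT convolution, and the
#' \eqn{\delta(\varepsilon)} hockey-stick curve is inverted by bisection; the
#' reported \eqn{\varepsilon} covers the worse of the two directions.
#'
#' @param sigma Noise multiplier (noise sd / clipping norm); `sigma = 0` means
#'   no noise and returns `Inf`.
#' @param q Poisson subsampling rate in `(0, 1]`.
#' @param iterations Number of composed steps `T >= 1`.
#' @param delta Target `delta` in `(0, 1)`.
#' @param grid_points Number of PLD grid points (power of two).
#' @return The privacy parameter `epsilon` (a single number).
#' @export
compute_epsilon <- function(sigma, q, iterations, delta, grid_points = 2^18) {
  stopifnot(q > 0, q <= 1, iterations >= 1, delta > 0, delta < 1)
  if (sigma <= 0) return(Inf)
  grid <- pld_grid(sigma, q, iterations, delta, grid_points)
  eps_needed <- vapply(c("remove", "add"), function(dir) {
    mass <- pld_step_mass(grid, sigma, q, dir)
    dfun <- pld_delta_fun(pld_compose(grid, mass, iterations))
    if (dfun(0) <= delta) return(0)
    lo <- 0
    hi <- grid$L
    if (dfun(hi) > delta) stop("epsilon exceeds the PLD grid range")
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (dfun(mid) > delta) lo <- mid else hi <- mid
    }
    hi
  }, numeric(1))
  max(eps_needed)
}

#' Renyi-DP upper bound for the subsampled Gaussian mechanism
#'
#' Independent, looser accounting route used to cross-check the
#' privacy-loss-distribution accountant: per-step Renyi divergence bounds of
#' the Poisson-subsampled Gaussian at integer orders (the binomial-expansion
#' bound), linear composition over iterations, and the standard
#' RDP-to-approximate-DP conversion
#' \eqn{\varepsilon = T\varepsilon_\alpha + \log(1/\delta)/(\alpha - 1)},
#' minimized over orders. Always at or above the PLD accountant's value.
#'
#' @inheritParams compute_epsilon
#' @param orders Integer Renyi orders to scan.
#' @return An upper bound on `epsilon`.
#' @export
rdp_epsilon <- function(sigma, q, iterations, delta, orders = 2:256) {
  stopifnot(q > 0, q <= 1, delta > 0, delta < 1)
  if (sigma <= 0) return(Inf)
  eps_alpha <- vapply(orders, function(alpha) {
    if (q == 1) {
      alpha / (2 * sigma^2)
    } else {
      k <- 0:alpha
      lt <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
        k * (k - 1) / (2 * sigma^2)
      m <- max(lt)
      (m + log(sum(exp(lt - m)))) / (alpha - 1)
    }
  }, numeric(1))
  min(iterations * eps_alpha + log(1 / delta) / (orders - 1))
}

#' Calibrate the noise multiplier to a target privacy budget
#'
#' Inverts [compute_epsilon()] by bisection in `sigma`: returns the smallest
#' noise multiplier (on the bisection grid) whose realized privacy cost does
#' not exceed `epsilon_target`, with the guarantee that the realized epsilon
#' lies in `(0.999 * epsilon_target, epsilon_target]`.
#'
#' @param epsilon_target Positive target `epsilon`.
#' @param delta Target `delta`.
#' @param q Poisson subsampling rate.
#' @param iterations Number of steps.
#' @param sigma_range Bracketing interval searched for `sigma`.
#' @return The calibrated noise multiplier.
#' @export
calibrate_noise <- function(epsilon_target, delta, q, iterations,
                            sigma_range = c(0.2, 400)) {
  stopifnot(epsilon_target > 0)
  lo <- sigma_range[1]
  hi <- sigma_range[2]
  eps_hi <- compute_epsilon(hi, q, iterations, delta)
  if (eps_hi > epsilon_target) {
    stop("epsilon_target ", epsilon_target, " unreachable with sigma <= ", hi)
  }
  if (compute_epsilon(lo, q, iterations, delta) <= epsilon_target) {
    stop("sigma_range lower bound already meets the target; widen the range")
  }
  # f(sigma) = epsilon is decreasing; shrink [lo, hi] until the hi endpoint
  # realizes epsilon within the guaranteed band.
  eps_cur <- eps_hi
  for (i in 1:60) {
    if (eps_cur > 0.999 * epsilon_target) break
    mid <- (lo + hi) / 2
    eps_mid <- compute_epsilon(mid, q, iterations, delta)
    if (eps_mid <= epsilon_target) {
      hi <- mid
      eps_cur <- eps_mid
    } else {
      lo <- mid
    }
  }
  if (!(eps_cur <= epsilon_target && eps_cur > 0.999 * epsilon_target)) {
    stop("calibration failed to land in the target epsilon band")
  }
  hi
}

#' Exact Gaussian-mechanism delta(epsilon) curve
#'
#' Closed-form hockey-stick divergence of the (unsubsampled, single-step)
#' Gaussian mechanism with sensitivity 1:
#' \eqn{\delta(\varepsilon) = \Phi(1/(2\sigma) - \varepsilon\sigma)
#' - e^{\varepsilon}\Phi(-1/(2\sigma) - \varepsilon\sigma)}. Used as the
#' analytic oracle for the accountant at `q = 1`, `iterations = 1`.
#'
#' @param epsilon Privacy parameter.
#' @param sigma Noise multiplier.
#' @return `delta` for the given `epsilon`.
#' @export
gaussian_mechanism_delta <- function(epsilon, sigma) {
  stats::pnorm(1 / (2 * sigma) - epsilon * sigma) -
    exp(epsilon) * stats::pnorm(-1 / (2 * sigma) - epsilon * sigma)
}
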