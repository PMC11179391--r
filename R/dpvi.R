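#' Privacy parameters for DP variational inference
#'
#' The contract between the DP-SGD training loop and the privacy accountant:
#' per-example gradients are clipped to L2 norm `clip_norm`, summed, and
#' perturbed with Gaussian noise of per-coordinate standard deviation
#' `noise_multiplier * clip_norm`, once per iteration on a Poisson-subsampled
#' batch (each record included independently with probability
#' `subsampling_ratio`). If `noise_multiplier` is `NULL` it is calibrated with
#' [calibrate_noise()] so that the `iterations`-fold composition meets
#' `(epsilon, delta)`; the realized epsilon reported by the accountant is
#' stored alongside.
#'
#' @param epsilon Target privacy budget (default 1, the conventional setting).
#' @param delta Target delta (default `1e-6`).
#' @param clip_norm Per-example gradient clipping norm `C > 0`.
#' @param noise_multiplier Noise multiplier `sigma >= 0`, or `NULL` to
#'   calibrate from `epsilon`.
#' @param subsampling_ratio Poisson batch inclusion probability `q` in `(0, 1]`.
#' @param iterations Number of DP-SGD iterations `T`.
#' @return An object of class `privacy_params`.
#' @export
privacy_params <- function(epsilon = 1, delta = 1e-6, clip_norm = 2,
                           noise_multiplier = NULL, subsampling_ratio = 0.1,
                           iterations = 2000) {
  stopifnot(epsilon >= 0, delta >= 0, delta <= 1, clip_norm > 0,
            subsampling_ratio > 0, subsampling_ratio <= 1, iterations >= 1)
  structure(
    list(
      epsilon = epsilon,
      delta = delta,
      clip_norm = clip_norm,
      noise_multiplier = noise_multiplier,
      subsampling_ratio = subsampling_ratio,
      iterations = as.integer(iterations),
      realized_epsilon = NULL
    ),
    class = "privacy_params"
  )
}

#' Calibrate (or account for) the noise multiplier of a `privacy_params`
#'
#' Fills in `noise_multiplier` from the `(epsilon, delta)` target when absent,
#' and records the realized epsilon reported by the accountant either way.
#'
#' @param pp A [privacy_params()] object.
#' @return The same object with `noise_multiplier` and `realized_epsilon` set.
#' @export
calibrate_privacy <- function(pp) {
  stopifnot(inherits(pp, "privacy_params"))
  if (is.null(pp$noise_multiplier)) {
    pp$noise_multiplier <- calibrate_noise(pp$epsilon, pp$delta,
                                           pp$subsampling_ratio, pp$iterations)
  }
  pp$realized_epsilon <- compute_epsilon(pp$noise_multiplier,
                                         pp$subsampling_ratio,
                                         pp$iterations, pp$delta)
  pp
}

#' @export
print.privacy_params <- function(x, ...) {
  cat("<privacy_params> target (epsilon, delta) = (", x$epsilon, ", ",
      format(x$delta), ")\n  clip C = ", x$clip_norm,
      "  sigma = ", if (is.null(x$noise_multiplier)) "(uncalibrated)" else
        format(x$noise_multiplier),
      "  q = ", x$subsampling_ratio, "  T = ", x$iterations, "\n", sep = "")
  if (!is.null(x$realized_epsilon)) {
    cat("  realized epsilon =", format(x$realized_epsilon), "\n")
  }
  invisible(x)
}

# ---- unconstrained parameter layout -----------------------------------------

# Index layout of the unconstrained parameter vector z:
#   mixture-weight sticks (R-1), then per-component per-feature categorical
#   sticks (L_j - 1 each), then regression weights (p, identity transform).
vp_spec <- function(mixture_components, level_counts) {
  R <- as.integer(mixture_components)
  level_counts <- as.integer(level_counts)
  d <- length(level_counts)
  p <- 1L + sum(level_counts - 1L)
  pos <- 0L
  idx_pi <- if (R > 1L) pos + seq_len(R - 1L) else integer(0)
  pos <- pos + length(idx_pi)
  idx_theta <- vector("list", R)
  for (r in seq_len(R)) {
    idx_theta[[r]] <- vector("list", d)
    for (j in seq_len(d)) {
      len <- level_counts[j] - 1L
      idx_theta[[r]][[j]] <- if (len > 0L) pos + seq_len(len) else integer(0)
      pos <- pos + len
    }
  }
  idx_w <- pos + seq_len(p)
  pos <- pos + p
  list(R = R, level_counts = level_counts, d = d, p = p,
       idx_pi = idx_pi, idx_theta = idx_theta, idx_w = idx_w, n_par = pos)
}

# Unconstrained z -> constrained parameters (plus break fractions for grads).
vp_transform <- function(z, spec) {
  pi_sb <- sb_forward(z[spec$idx_pi])
  theta <- v_theta <- vector("list", spec$R)
  for (r in seq_len(spec$R)) {
    theta[[r]] <- v_theta[[r]] <- vector("list", spec$d)
    for (j in seq_len(spec$d)) {
      sb <- sb_forward(z[spec$idx_theta[[r]][[j]]])
      theta[[r]][[j]] <- sb$p
      v_theta[[r]][[j]] <- sb$v
    }
  }
  list(pi = pi_sb$p, v_pi = pi_sb$v, theta = theta, v_theta = v_theta,
       w = z[spec$idx_w])
}

# Constrained parameters -> unconstrained z.
vp_inverse <- function(params, spec) {
  z <- numeric(spec$n_par)
  z[spec$idx_pi] <- sb_inverse(params$mixture_weights)
  for (r in seq_len(spec$R)) {
    for (j in seq_len(spec$d)) {
      z[spec$idx_theta[[r]][[j]]] <-
        sb_inverse(params$component_categoricals[[r]][[j]])
    }
  }
  z[spec$idx_w] <- params$regression_weights
  z
}

vp_gen_params <- function(tr) {
  generative_params(tr$pi, tr$theta, tr$w)
}

# ---- model log-density and gradients ----------------------------------------

# Joint log p(batch | T(z)) pieces and the shared (prior + Jacobian) term.
# codes: B x d integer matrix; X: B x p design; y: length-B outcomes.
vp_log_lik <- function(tr, codes, X, y) {
  gp <- list(mixture_weights = tr$pi, component_categoricals = tr$theta)
  ll_x <- mixture_loglik(codes, gp)$loglik
  eta <- pmin(drop(X %*% tr$w), 30)
  ll_y <- y * eta - exp(eta) - lgamma(y + 1)
  sum(ll_x + ll_y)
}

# log p(T(z)) + log |J(z)|: uniform Dirichlet prior on every simplex (constant
# density) plus stick-breaking Jacobians, Gaussian prior on w.
vp_log_prior_jac <- function(tr, spec, w_prior_scale) {
  lp <- lgamma(spec$R) + sb_log_det_jac(tr$v_pi)
  for (r in seq_len(spec$R)) {
    for (j in seq_len(spec$d)) {
      lp <- lp + lgamma(spec$level_counts[j]) + sb_log_det_jac(tr$v_theta[[r]][[j]])
    }
  }
  lp + sum(stats::dnorm(tr$w, 0, w_prior_scale, log = TRUE))
}

# Gradient of vp_log_prior_jac with respect to z.
vp_common_grad <- function(tr, spec, w_prior_scale) {
  cg <- numeric(spec$n_par)
  cg[spec$idx_pi] <- sb_log_det_jac_grad(tr$v_pi)
  for (r in seq_len(spec$R)) {
    for (j in seq_len(spec$d)) {
      cg[spec$idx_theta[[r]][[j]]] <- sb_log_det_jac_grad(tr$v_theta[[r]][[j]])
    }
  }
  cg[spec$idx_w] <- -tr$w / w_prior_scale^2
  cg
}

# Per-example gradients of log p(x_i, y_i | T(z)) with respect to z.
# Returns a B x n_par matrix.
vp_per_example_grads <- function(tr, spec, codes, X, y) {
  B <- nrow(codes)
  G <- matrix(0, B, spec$n_par)
  if (B == 0) return(G)
  gp <- list(mixture_weights = tr$pi, component_categoricals = tr$theta)
  ml <- mixture_loglik(codes, gp, responsibilities = TRUE)
  resp <- ml$resp
  R <- spec$R
  # mixture-weight sticks: (1 - v_k) resp_k - v_k * sum_{r > k} resp_r
  if (R > 1L) {
    csum <- resp
    if (R > 2L) for (r in 2:R) csum[, r] <- csum[, r] + csum[, r - 1L]
    k <- seq_len(R - 1L)
    Gpi <- resp[, k, drop = FALSE] *
      matrix(1 - tr$v_pi, B, R - 1L, byrow = TRUE) -
      (1 - csum[, k, drop = FALSE]) * matrix(tr$v_pi, B, R - 1L, byrow = TRUE)
    G[, spec$idx_pi] <- Gpi
  }
  # categorical sticks: resp_r * ((1 - v_k) 1[c = k] - v_k 1[c > k])
  for (j in seq_len(spec$d)) {
    L <- spec$level_counts[j]
    if (L < 2L) next
    cc <- codes[, j] + 1L
    ks <- seq_len(L - 1L)
    Aeq <- outer(cc, ks, "==") + 0
    Agt <- outer(cc, ks, ">") + 0
    for (r in seq_len(R)) {
      v <- tr$v_theta[[r]][[j]]
      base <- t(t(Aeq) * (1 - v)) - t(t(Agt) * v)
      G[, spec$idx_theta[[r]][[j]]] <- base * resp[, r]
    }
  }
  # regression weights: (y - lambda) x
  eta <- pmin(drop(X %*% tr$w), 30)
  G[, spec$idx_w] <- (y - exp(eta)) * X
  G
}

# ---- ELBO estimate ----------------------------------------------------------

vp_entropy <- function(log_scale) {
  sum(log_scale) + 0.5 * length(log_scale) * (1 + log(2 * pi))
}

#' Single-sample reparameterized ELBO estimate
#'
#' Draws one standard-normal vector, maps it through the posterior's
#' location/scale to an unconstrained parameter point `z`, and evaluates
#' `E_q[log p(D, theta)] - E_q[log q(theta)]` as
#' `(n_total / |batch|) * sum_i log p(x_i, y_i | T(z)) + log p(T(z)) +
#' log |J(z)| + H[q]`, with the per-record likelihood term rescaled from the
#' minibatch to the full data size and the Gaussian entropy `H[q]` in closed
#' form. An empty batch reduces the estimate to the prior-plus-entropy terms.
#'
#' @param post A `dpvi_posterior` (see [fit_dpvi()]).
#' @param batch Cohort tibble (possibly 0 rows) with `x1..xd`, `y`.
#' @param n_total Full training-set size the likelihood term is rescaled to.
#' @param seed Integer seed for the single standard-normal draw.
#' @param eps Optionally, the standard-normal vector itself (length
#'   `2 * n_par` posterior coordinates / `n_par` values), overriding `seed`.
#' @return A single number.
#' @export
elbo_estimate <- function(post, batch, n_total, seed = 1, eps = NULL) {
  spec <- post$spec
  if (is.null(eps)) {
    eps <- withr::with_seed(derive_seed(seed, "elbo"), stats::rnorm(spec$n_par))
  }
  z <- post$loc + exp(post$log_scale) * eps
  tr <- vp_transform(z, spec)
  B <- nrow(batch)
  lik <- if (B > 0) {
    codes <- codes_matrix(batch, spec$d)
    X <- encode_dataset(batch, feature_encoding(spec$level_counts))
    (n_total / B) * vp_log_lik(tr, codes, X, as.numeric(batch$y))
  } else 0
  lik + vp_log_prior_jac(tr, spec, post$w_prior_scale) + vp_entropy(post$log_scale)
}

# ---- DP-SGD primitives ------------------------------------------------------

#' Clip per-example gradients and add Gaussian noise
#'
#' Rescales each per-example gradient by `min(1, C / ||g||_2)`, sums them, and
#' adds independent Gaussian noise with per-coordinate standard deviation
#' `noise_multiplier * C`. This is the only point where per-example
#' information is aggregated; everything downstream sees only the returned
#' vector.
#'
#' @param per_example_grads Numeric matrix with one row per example (or a list
#'   of equal-length vectors).
#' @param clip_norm Clipping norm `C > 0`.
#' @param noise_multiplier Noise multiplier `sigma >= 0`; 0 adds no noise (and
#'   consumes no random numbers).
#' @param seed Integer seed for the noise draw, or `NULL` to use the current
#'   RNG state.
#' @return The clipped, noised gradient sum (numeric vector).
#' @export
clip_and_noise <- function(per_example_grads, clip_norm, noise_multiplier,
                           seed = NULL) {
  stopifnot(clip_norm > 0, noise_multiplier >= 0)
  g <- if (is.list(per_example_grads)) {
    do.call(rbind, per_example_grads)
  } else {
    per_example_grads
  }
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  total <- if (nrow(g) == 0) {
    numeric(ncol(g))
  } else {
    norms <- sqrt(rowSums(g^2))
    scale <- pmin(1, clip_norm / pmax(norms, .Machine$double.xmin))
    colSums(g * scale)
  }
  if (noise_multiplier > 0) {
    noise_draw <- function() stats::rnorm(length(total), 0,
                                          noise_multiplier * clip_norm)
    noise <- if (is.null(seed)) noise_draw() else {
      withr::with_seed(derive_seed(seed, "noise"), noise_draw())
    }
    total <- total + noise
  }
  total
}

# ---- the DPVI training loop -------------------------------------------------

#' Fit the generative model with differentially private variational inference
#'
#' Mean-field Gaussian variational inference on the unconstrained
#' (stick-breaking) parameterization of the mixture-of-categoricals plus
#' Poisson-regression generative model, trained with DP stochastic gradient
#' ascent: each iteration Poisson-subsamples a batch at rate `q`, computes
#' per-example reparameterized ELBO gradients (each example's likelihood
#' gradient plus its `1/n` share of the prior, Jacobian and entropy
#' gradients), clips them to norm `C`, sums, adds Gaussian noise of scale
#' `sigma * C`, divides by the expected batch size `q * n`, and takes an Adam
#' step. Randomness is organized as named streams (batch selection, ELBO
#' draw, noise) derived from the master seed, so runs are bitwise
#' reproducible and the noise stream can be switched off without disturbing
#' the others.
#'
#' @param train Training tibble with `x1..xd`, `y`.
#' @param level_counts Categories per feature (codes 0-based).
#' @param pp A [privacy_params()]; calibrated with [calibrate_privacy()] first
#'   if its `noise_multiplier` is `NULL`.
#' @param mixture_components Number of mixture components `R` (default 16).
#' @param learn_rate Adam step size (default 0.01).
#' @param w_prior_scale Standard deviation of the Gaussian prior on the
#'   regression weights (default 2; simplexes carry a uniform Dirichlet prior).
#' @param init_scale Initial posterior scale (default 0.1); locations start at
#'   0, i.e. uniform simplexes and zero weights.
#' @param seed Master seed.
#' @param trace Record the location trajectory (`n_iter x n_par` matrix).
#' @param optimizer_hook Optional function called each iteration with the
#'   (already clipped and noised) gradient vector the optimizer receives;
#'   for inspection only.
#' @return An object of class `dpvi_posterior`: fields `loc`, `log_scale`,
#'   `spec`, `privacy` (including realized epsilon), `w_prior_scale`, `seed`,
#'   and optionally `trace`.
#' @export
fit_dpvi <- function(train, level_counts, pp,
                     mixture_components = 16, learn_rate = 0.01,
                     w_prior_scale = 2, init_scale = 0.1, seed = 1,
                     trace = FALSE, optimizer_hook = NULL) {
  pp <- calibrate_privacy(pp)
  dpvi_engine(train, level_counts, pp, mixture_components, learn_rate,
              w_prior_scale, init_scale, seed, trace, optimizer_hook,
              private = TRUE)
}

#' Non-private stochastic variational inference baseline
#'
#' The same variational model, subsampling, initialization and optimizer as
#' [fit_dpvi()], but the raw per-example gradient sum is used directly: no
#' clipping, no noise. With `noise_multiplier = 0` and an inactive clipping
#' norm, [fit_dpvi()] reproduces this trajectory exactly under the same seed.
#'
#' @inheritParams fit_dpvi
#' @param subsampling_ratio Poisson batch rate `q`.
#' @param iterations Number of iterations.
#' @return A `dpvi_posterior` (with a privacy field marking the fit as
#'   non-private, epsilon infinite).
#' @export
fit_svi <- function(train, level_counts, subsampling_ratio = 0.1,
                    iterations = 2000, mixture_components = 16,
                    learn_rate = 0.01, w_prior_scale = 2, init_scale = 0.1,
                    seed = 1, trace = FALSE) {
  pp <- privacy_params(epsilon = Inf, delta = 1e-6, clip_norm = 1,
                       noise_multiplier = 0,
                       subsampling_ratio = subsampling_ratio,
                       iterations = iterations)
  pp$realized_epsilon <- Inf
  dpvi_engine(train, level_counts, pp, mixture_components, learn_rate,
              w_prior_scale, init_scale, seed, trace, NULL, private = FALSE)
}

dpvi_engine <- function(train, level_counts, pp, mixture_components,
                        learn_rate, w_prior_scale, init_scale, seed, trace,
                        optimizer_hook, private) {
  spec <- vp_spec(mixture_components, level_counts)
  n <- nrow(train)
  if (n == 0) stop("training data is empty")
  codes_all <- codes_matrix(train, spec$d)
  X_all <- encode_dataset(train, feature_encoding(level_counts))
  y_all <- as.numeric(train$y)
  q <- pp$subsampling_ratio
  T_ <- pp$iterations
  C <- pp$clip_norm
  sig <- pp$noise_multiplier
  P <- spec$n_par
  loc <- numeric(P)
  log_scale <- rep(log(init_scale), P)
  m1 <- u1 <- numeric(2 * P)  # Adam state over (loc, log_scale)
  b1 <- 0.9; b2 <- 0.999; eps_opt <- 1e-8
  tr_mat <- if (trace) matrix(NA_real_, T_, P) else NULL
  for (t_ in seq_len(T_)) {
    idx <- withr::with_seed(derive_seed(seed, "batch", t_),
                            which(stats::runif(n) < q))
    epsd <- withr::with_seed(derive_seed(seed, "draw", t_), stats::rnorm(P))
    scl <- exp(log_scale)
    z <- loc + scl * epsd
    tr <- vp_transform(z, spec)
    cg <- vp_common_grad(tr, spec, w_prior_scale)
    B <- length(idx)
    G <- vp_per_example_grads(tr, spec,
                              codes_all[idx, , drop = FALSE],
                              X_all[idx, , drop = FALSE], y_all[idx])
    # each example carries its 1/n share of prior + Jacobian (+ entropy below)
    Gmu <- G + matrix(cg / n, B, P, byrow = TRUE)
    Glog <- Gmu * matrix(scl * epsd, B, P, byrow = TRUE) + 1 / n
    Gfull <- cbind(Gmu, Glog)
    if (!all(is.finite(Gfull))) {
      stop("non-finite per-example gradient at iteration ", t_)
    }
    gsum <- if (private) {
      clip_and_noise(Gfull, C, sig, seed = derive_seed(seed, "it", t_))
    } else {
      colSums(Gfull)
    }
    if (!is.null(optimizer_hook)) optimizer_hook(gsum)
    g <- gsum / (q * n)
    m1 <- b1 * m1 + (1 - b1) * g
    u1 <- b2 * u1 + (1 - b2) * g^2
    mhat <- m1 / (1 - b1^t_)
    uhat <- u1 / (1 - b2^t_)
    step <- learn_rate * mhat / (sqrt(uhat) + eps_opt)
    loc <- loc + step[seq_len(P)]
    log_scale <- log_scale + step[P + seq_len(P)]
    if (trace) tr_mat[t_, ] <- loc
  }
  structure(
    list(loc = loc, log_scale = log_scale, spec = spec, privacy = pp,
         w_prior_scale = w_prior_scale, learn_rate = learn_rate,
         n_train = n, seed = seed, trace = tr_mat),
    class = "dpvi_posterior"
  )
}

#' @export
print.dpvi_posterior <- function(x, ...) {
  cat("<dpvi_posterior> R =", x$spec$R, " d =", x$spec$d,
      " unconstrained dim =", x$spec$n_par, "\n")
  if (!is.null(x$privacy$realized_epsilon)) {
    cat("  privacy: epsilon =", format(x$privacy$realized_epsilon),
        " delta =", format(x$privacy$delta),
        " sigma =", format(x$privacy$noise_multiplier), "\n")
  }
  invisible(x)
}

#' Draw generative-model parameters from a fitted posterior
#'
#' Samples an unconstrained vector from the mean-field Gaussian and maps it
#' through the stick-breaking transform to valid generative parameters.
#'
#' @param post A `dpvi_posterior`.
#' @param seed Integer seed.
#' @return A [generative_params()] object.
#' @export
posterior_draw <- function(post, seed = 1) {
  if (!all(is.finite(post$log_scale))) stop("posterior scales are not finite")
  eps <- withr::with_seed(derive_seed(seed, "posterior-draw"),
                          stats::rnorm(post$spec$n_par))
  z <- post$loc + exp(post$log_scale) * eps
  vp_gen_params(vp_transform(z, post$spec))
}

#' Posterior-mean generative parameters
#'
#' Maps the posterior location (the mean in unconstrained space) through the
#' transform; a convenient point estimate of the fitted generative model.
#'
#' @param post A `dpvi_posterior`.
#' @return A [generative_params()] object.
#' @export
posterior_mean_params <- function(post) {
  vp_gen_params(vp_transform(post$loc, post$spec))
}
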