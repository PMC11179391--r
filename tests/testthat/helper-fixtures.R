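# Shared fixture builders: everything is generated in code at test time.

# A random valid gen_params with given shape.
random_gen_params <- function(R, level_counts, seed = 1, w_scale = 0.5) {
  withr::with_seed(seed, {
    pi_ <- rgamma(R, 1) + 0.05
    pi_ <- pi_ / sum(pi_)
    theta <- lapply(seq_len(R), function(r) {
      lapply(level_counts, function(L) {
        g <- rgamma(L, 1) + 0.05
        g / sum(g)
      })
    })
    p <- 1L + sum(level_counts - 1L)
    generative_params(pi_, theta, rnorm(p, 0, w_scale))
  })
}

# A small random cohort tibble with valid codes.
random_cohort <- function(n, level_counts, seed = 1, p_y = 0.3) {
  withr::with_seed(seed, {
    out <- tibble::as_tibble(lapply(seq_along(level_counts), function(j) {
      sample.int(level_counts[j], n, replace = TRUE) - 1L
    }), .name_repair = ~ paste0("x", seq_along(level_counts)))
    out$y <- rbinom(n, 1, p_y)
    out
  })
}

# Central finite-difference gradient of f at x.
numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Mixture-averaged marginal distribution of feature j implied by gen_params.
model_marginal <- function(params, j) {
  m <- 0
  for (r in seq_along(params$mixture_weights)) {
    m <- m + params$mixture_weights[r] * params$component_categoricals[[r]][[j]]
  }
  m
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# Empirical marginal of feature j from a cohort tibble.
empirical_marginal <- function(data, j, L) {
  tabulate(data[[paste0("x", j)]] + 1L, nbins = L) / nrow(data)
}
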