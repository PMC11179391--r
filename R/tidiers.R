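#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Poisson regression fit
#'
#' @param x A `poisson_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` and a `dropped` flag
#'   for design columns removed as unobserved.
#' @export
tidy.poisson_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(unname(x$variance)),
    dropped = names(x$coefficients) %in% x$dropped
  )
}

#' @rdname tidy.poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations, nobs = x$nobs,
                 n_dropped = length(x$dropped))
}

#' Tidy a Rubin's-rules combination
#'
#' @param x A `rubin_estimate`.
#' @param ... Unused.
#' @return A tibble with per-coefficient `term`, `estimate`, `std.error`,
#'   `between`, `within`, and the variance `rule` applied (`"minus"` or the
#'   conservative `"plus"` fallback).
#' @export
tidy.rubin_estimate <- function(x, ...) {
  tibble::tibble(
    term = names(x$mean) %||% paste0("w", seq_along(x$mean) - 1L),
    estimate = unname(x$mean),
    std.error = sqrt(unname(x$variance)),
    between = unname(x$between),
    within = unname(x$within),
    rule = unname(x$rule)
  )
}

#' @rdname tidy.rubin_estimate
#' @export
glance.rubin_estimate <- function(x, ...) {
  tibble::tibble(K = x$K, n_plus_rule = sum(x$rule == "plus"))
}

#' Tidy a fitted DP variational posterior
#'
#' @param x A `dpvi_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per unconstrained coordinate: `block`
#'   (`"mixture_weights"`, `"component_categoricals"`, `"regression_weights"`),
#'   `location`, `scale`.
#' @export
tidy.dpvi_posterior <- function(x, ...) {
  spec <- x$spec
  block <- character(spec$n_par)
  block[spec$idx_pi] <- "mixture_weights"
  for (r in seq_len(spec$R)) {
    for (j in seq_len(spec$d)) {
      block[spec$idx_theta[[r]][[j]]] <- "component_categoricals"
    }
  }
  block[spec$idx_w] <- "regression_weights"
  tibble::tibble(coordinate = seq_len(spec$n_par), block = block,
                 location = x$loc, scale = exp(x$log_scale))
}

#' @rdname tidy.dpvi_posterior
#' @export
glance.dpvi_posterior <- function(x, ...) {
  pp <- x$privacy
  tibble::tibble(
    n_par = x$spec$n_par, mixture_components = x$spec$R,
    n_train = x$n_train,
    epsilon = pp$realized_epsilon %||% NA_real_,
    delta = pp$delta, noise_multiplier = pp$noise_multiplier %||% NA_real_,
    subsampling_ratio = pp$subsampling_ratio, iterations = pp$iterations
  )
}
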