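#' Parameters of the two-part generative model
#'
#' The generative model for a party's cohort has two parts: the covariates
#' follow a mixture of product-categoricals,
#' \deqn{p(x \mid \theta, \pi) = \sum_r \pi_r \prod_j p(x_j \mid \theta_j^{(r)}),}
#' and the binary test outcome follows the same Poisson regression used for the
#' downstream analysis, \eqn{y \sim \mathrm{Poisson}(\lambda)} with
#' \eqn{\lambda = \exp(w^\top \tilde x)} and \eqn{\tilde x} the dummy-encoded
#' covariate vector (see [feature_encoding()]).
#'
#' @param mixture_weights Numeric simplex of length `R` (mixture weights).
#' @param component_categoricals List of length `R`; element `r` is a list of
#'   `d` numeric simplexes, the categorical parameters of each feature within
#'   mixture component `r`.
#' @param regression_weights Numeric vector of length `p`, the Poisson
#'   regression weights on the encoded covariates (intercept first).
#' @return An object of class `gen_params`.
#' @export
generative_params <- function(mixture_weights, component_categoricals,
                              regression_weights) {
  pi_ <- as.numeric(mixture_weights)
  if (any(pi_ < 0) || abs(sum(pi_) - 1) > 1e-9) {
    stop("`mixture_weights` must be non-negative and sum to 1 (tol 1e-9)")
  }
  theta <- lapply(component_categoricals, function(comp) lapply(comp, as.numeric))
  if (length(theta) != length(pi_)) {
    stop("`component_categoricals` must have one element per mixture component")
  }
  d <- length(theta[[1]])
  for (comp in theta) {
    if (length(comp) != d) stop("all components must cover the same features")
    for (th in comp) {
      if (any(th < 0) || abs(sum(th) - 1) > 1e-9) {
        stop("each categorical parameter vector must be a simplex (tol 1e-9)")
      }
    }
  }
  structure(
    list(
      mixture_weights = pi_,
      component_categoricals = theta,
      regression_weights = as.numeric(regression_weights)
    ),
    class = "gen_params"
  )
}

#' @export
print.gen_params <- function(x, ...) {
  cat("<gen_params> mixture of product-categoricals + Poisson regression\n")
  cat("  components R =", length(x$mixture_weights),
      " features d =", length(x$component_categoricals[[1]]),
      " encoded length p =", length(x$regression_weights), "\n")
  invisible(x)
}

gp_levels <- function(params) {
  vapply(params$component_categoricals[[1]], length, integer(1))
}

#' Dummy encoding of categorical features
#'
#' Describes how category-code tuples enter the regression: a leading
#' intercept, then for every feature a one-hot block with the reference level
#' dropped, so the encoded length is `p = 1 + sum(level_counts - 1)`. The
#' reference level is category code 0 for every feature. Dummy coding (rather
#' than full one-hot) keeps the Poisson maximum-likelihood problem
#' identifiable.
#'
#' @param level_counts Integer vector of length `d`; number of categories per
#'   feature. Category codes are 0-based: code `c` of feature `j` lies in
#'   `[0, level_counts[j])`.
#' @param drop_features Optional integer vector of feature indices to exclude
#'   from the encoding entirely (used, e.g., to fit an analysis model that
#'   ignores a sensitive covariate).
#' @return An object of class `feature_encoding` with fields `level_counts`,
#'   `drop_features`, `p`, and per-column `names`.
#' @export
feature_encoding <- function(level_counts, drop_features = integer(0)) {
  level_counts <- as.integer(level_counts)
  if (any(level_counts < 1)) stop("`level_counts` must be >= 1")
  drop_features <- as.integer(drop_features)
  used <- setdiff(seq_along(level_counts), drop_features)
  nm <- "(Intercept)"
  for (j in used) {
    if (level_counts[j] > 1L) {
      nm <- c(nm, paste0("x", j, "_", seq_len(level_counts[j] - 1L)))
    }
  }
  structure(
    list(
      level_counts = level_counts,
      drop_features = drop_features,
      p = length(nm),
      names = nm
    ),
    class = "feature_encoding"
  )
}

#' @export
print.feature_encoding <- function(x, ...) {
  cat("<feature_encoding> d =", length(x$level_counts),
      " levels = (", paste(x$level_counts, collapse = ", "), ")",
      " p =", x$p, "\n")
  invisible(x)
}

codes_matrix <- function(data, d) {
  cols <- paste0("x", seq_len(d))
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("dataset is missing feature columns: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "integer"
  m
}

#' Encode a dataset's categorical features for regression
#'
#' @param data A cohort tibble with integer feature columns `x1..xd` (0-based
#'   category codes).
#' @param enc A [feature_encoding()].
#' @return A numeric design matrix with `nrow(data)` rows and `enc$p` columns:
#'   intercept followed by reference-dropped dummy columns.
#' @export
encode_dataset <- function(data, enc) {
  stopifnot(inherits(enc, "feature_encoding"))
  d <- length(enc$level_counts)
  codes <- codes_matrix(data, d)
  for (j in seq_len(d)) {
    bad <- codes[, j] < 0L | codes[, j] >= enc$level_counts[j]
    if (any(bad)) {
      stop("feature x", j, " has codes outside [0, ", enc$level_counts[j],
           ") in ", sum(bad), " record(s)")
    }
  }
  n <- nrow(codes)
  X <- matrix(0, n, enc$p, dimnames = list(NULL, enc$names))
  X[, 1] <- 1
  col <- 1L
  for (j in setdiff(seq_len(d), enc$drop_features)) {
    L <- enc$level_counts[j]
    if (L > 1L) {
      for (l in seq_len(L - 1L)) {
        col <- col + 1L
        X[, col] <- as.numeric(codes[, j] == l)
      }
    }
  }
  X
}

#' Encode a single record
#'
#' @param record Integer vector of `d` category codes (0-based).
#' @param enc A [feature_encoding()].
#' @return Numeric vector of length `enc$p`.
#' @export
encode_features <- function(record, enc) {
  df <- as.data.frame(as.list(as.integer(record)))
  names(df) <- paste0("x", seq_along(record))
  drop(encode_dataset(df, enc))
}

# Per-record mixture log-density and component responsibilities.
# codes: n x d integer matrix of 0-based codes.
mixture_loglik <- function(codes, params, responsibilities = FALSE) {
  R <- length(params$mixture_weights)
  d <- length(params$component_categoricals[[1]])
  n <- nrow(codes)
  lw <- matrix(log(params$mixture_weights), n, R, byrow = TRUE)
  for (r in seq_len(R)) {
    for (j in seq_len(d)) {
      lw[, r] <- lw[, r] + log(params$component_categoricals[[r]][[j]])[codes[, j] + 1L]
    }
  }
  mx <- apply(lw, 1, max)
  mx[!is.finite(mx)] <- 0  # all-components zero-probability rows
  ll <- mx + log(rowSums(exp(lw - mx)))
  out <- list(loglik = ll)
  if (responsibilities) out$resp <- exp(lw - ll)
  out
}

#' Log-density of the covariate mixture model
#'
#' Evaluates \eqn{\log \sum_r \pi_r \prod_j \theta_j^{(r)}[x_j]} for every
#' record, with the sum over components computed in log space (max-shifted)
#' so small per-feature probabilities do not underflow. Records with zero
#' probability under every component return `-Inf`.
#'
#' @param data Cohort tibble with feature columns `x1..xd`.
#' @param params A [generative_params()] object.
#' @return Numeric vector of per-record log-densities.
#' @export
log_prob_features <- function(data, params) {
  d <- length(params$component_categoricals[[1]])
  codes <- codes_matrix(data, d)
  levels <- gp_levels(params)
  for (j in seq_len(d)) {
    if (any(codes[, j] < 0L | codes[, j] >= levels[j])) {
      stop("feature x", j, " has codes outside [0, ", levels[j], ")")
    }
  }
  mixture_loglik(codes, params)$loglik
}

#' Poisson log-probability of outcomes given covariates
#'
#' \eqn{\log p(y \mid x, w) = y \ln\lambda - \lambda - \ln(y!)} with
#' \eqn{\lambda = \exp(w^\top \tilde x)}. The linear predictor is capped at 30
#' before exponentiation so extreme weight draws yield very negative but
#' finite log-probabilities.
#'
#' @param data Cohort tibble with feature columns `x1..xd`.
#' @param y Non-negative integer outcome vector (recycled if length 1).
#' @param w Regression weights, length `enc$p`.
#' @param enc A [feature_encoding()].
#' @return Numeric vector of per-record log-probabilities.
#' @export
log_prob_outcome <- function(data, y, w, enc) {
  X <- encode_dataset(data, enc)
  y <- as.numeric(y)
  if (length(y) == 1L) y <- rep(y, nrow(X))
  if (any(y < 0 | y != floor(y))) stop("`y` must be non-negative integers")
  eta <- pmin(drop(X %*% w), 30)
  y * eta - exp(eta) - lgamma(y + 1)
}

#' Most probable binary outcome under the Poisson analysis model
#'
#' Returns \eqn{\arg\max_{y \in \{0,1\}}} of the Poisson pmf at
#' \eqn{\lambda = \exp(w^\top \tilde x)}, which equals 1 exactly when
#' \eqn{\lambda > 1}; the tie at \eqn{\lambda = 1} resolves to 0. The argmax is
#' restricted to \{0, 1\} because the modelled outcome is a binary test result.
#'
#' @inheritParams log_prob_outcome
#' @return Integer vector of predicted outcomes in `{0, 1}`.
#' @export
predict_outcome <- function(data, w, enc) {
  X <- encode_dataset(data, enc)
  as.integer(drop(X %*% w) > 0)
}

# Shared outcome mapping: Poisson draw clipped to the binary support. Both the
# ground-truth cohort generator and the synthetic-data sampler go through this
# single code path.
sample_records <- function(params, n, enc) {
  R <- length(params$mixture_weights)
  levels <- gp_levels(params)
  d <- length(levels)
  if (n == 0L) {
    out <- tibble::as_tibble(matrix(integer(0), 0, d,
                                    dimnames = list(NULL, paste0("x", seq_len(d)))))
    out$y <- integer(0)
    return(out)
  }
  comp <- sample.int(R, n, replace = TRUE, prob = params$mixture_weights)
  codes <- matrix(0L, n, d)
  for (r in seq_len(R)) {
    idx <- which(comp == r)
    if (length(idx) == 0) next
    for (j in seq_len(d)) {
      codes[idx, j] <- sample.int(levels[j], length(idx), replace = TRUE,
                                  prob = params$component_categoricals[[r]][[j]]) - 1L
    }
  }
  colnames(codes) <- paste0("x", seq_len(d))
  out <- tibble::as_tibble(codes)
  eta <- pmin(drop(encode_dataset(out, enc) %*% params$regression_weights), 30)
  out$y <- pmin(stats::rpois(n, exp(eta)), 1L)
  out
}

#' Sample a synthetic dataset from generative-model parameters
#'
#' Draws `n` i.i.d. records: mixture component from \eqn{\pi}, each feature
#' from its component categorical, and the outcome from
#' \eqn{\mathrm{Poisson}(\exp(w^\top \tilde x))} clipped to `{0, 1}` so the
#' synthetic data keep the binary outcome schema of the real cohorts.
#'
#' @param params A [generative_params()] object.
#' @param n Number of records to draw. By convention a party samples synthetic
#'   replicates of the same size as its local training set.
#' @param seed Integer seed; the draw is deterministic given `(params, n, seed)`.
#' @return A cohort tibble with columns `x1..xd` and `y`.
#' @export
sample_synthetic <- function(params, n, seed) {
  stopifnot(inherits(params, "gen_params"), n >= 0)
  enc <- feature_encoding(gp_levels(params))
  if (length(params$regression_weights) != enc$p) {
    stop("`regression_weights` has length ", length(params$regression_weights),
         " but the encoding needs ", enc$p)
  }
  withr::with_seed(seed, sample_records(params, as.integer(n), enc))
}
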