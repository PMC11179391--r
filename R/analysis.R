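#' Fit the downstream Poisson regression by Newton iterations
#'
#' Maximum-likelihood fit of \eqn{y \sim \mathrm{Poisson}(\exp(w^\top \tilde x))}
#' on the dummy-encoded covariates, by Newton/Fisher scoring with step halving.
#' Convergence is declared when the maximum absolute score drops below `1e-8`
#' (or after 100 iterations, in which case the fit is flagged non-converged).
#' Coefficient variances are the diagonal of the inverse observed Fisher
#' information at the maximum.
#'
#' Dummy columns for category levels that never occur in `data` are all-zero
#' and make the design rank deficient; with `drop_unobserved = TRUE` (the
#' pipeline default) they are dropped before fitting and the returned
#' coefficient/variance vectors are padded with 0 at the dropped positions,
#' with the dropped column names recorded. Any remaining rank deficiency is an
#' error naming the collinear columns.
#'
#' @param data Cohort tibble with `x1..xd` and `y`.
#' @param enc A [feature_encoding()].
#' @param drop_unobserved Drop all-zero dummy columns instead of erroring.
#' @return An object of class `poisson_fit` with fields `coefficients`,
#'   `variance`, `converged`, `iterations`, `dropped`, `loglik`, `nobs`.
#' @export
fit_poisson_regression <- function(data, enc, drop_unobserved = FALSE) {
  if (nrow(data) == 0) stop("training data is empty")
  X <- encode_dataset(data, enc)
  y <- as.numeric(data$y)
  keep <- rep(TRUE, ncol(X))
  if (drop_unobserved) {
    keep <- colSums(abs(X)) > 0
  }
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    dep <- colnames(Xk)[qrX$pivot[(qrX$rank + 1L):ncol(Xk)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  fit <- poisson_newton(Xk, y)
  coef_full <- numeric(ncol(X))
  var_full <- numeric(ncol(X))
  coef_full[keep] <- fit$w
  var_full[keep] <- fit$v
  names(coef_full) <- names(var_full) <- colnames(X)
  structure(
    list(
      coefficients = coef_full,
      variance = var_full,
      converged = fit$converged,
      iterations = fit$iterations,
      dropped = colnames(X)[!keep],
      loglik = fit$loglik,
      nobs = nrow(X)
    ),
    class = "poisson_fit"
  )
}

# Newton/Fisher scoring core on a full-rank design.
poisson_newton <- function(X, y, tol = 1e-8, max_iter = 100L) {
  n <- nrow(X)
  p <- ncol(X)
  w <- numeric(p)
  w[1] <- log(max(mean(y), 1e-12))  # intercept at the marginal rate
  loglik <- function(w) {
    eta <- pmin(drop(X %*% w), 30)
    sum(y * eta - exp(eta)) - sum(lgamma(y + 1))
  }
  ll <- loglik(w)
  converged <- FALSE
  iter <- 0L
  if (all(y == 0)) {
    # MLE at -Inf intercept: degenerate, flagged rather than chased
    return(list(w = w, v = rep(NA_real_, p), converged = FALSE,
                iterations = 0L, loglik = ll))
  }
  info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- pmin(drop(X %*% w), 30)
    lam <- exp(eta)
    score <- drop(crossprod(X, y - lam))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    info <- crossprod(X, X * lam)
    step <- tryCatch(solve(info, score),
                     error = function(e) solve(info + 1e-10 * diag(p), score))
    # step halving keeps the log-likelihood non-decreasing
    t_ <- 1
    repeat {
      w_new <- w + t_ * step
      ll_new <- loglik(w_new)
      if (ll_new >= ll - 1e-12 || t_ < 1e-6) break
      t_ <- t_ / 2
    }
    w <- w_new
    ll <- ll_new
  }
  eta <- pmin(drop(X %*% w), 30)
  info <- crossprod(X, X * exp(eta))
  v <- tryCatch(diag(chol2inv(chol(info))),
                error = function(e) diag(solve(info + 1e-10 * diag(p))))
  list(w = w, v = v, converged = converged, iterations = iter, loglik = ll)
}

#' Combine replicate fits with Rubin's rules
#'
#' Given `K` fits of the same analysis model on `K` synthetic-data replicates,
#' combines them into a single Gaussian summary: element-wise mean
#' \eqn{\bar w_K}, between-replicate variance
#' \eqn{b = \frac{1}{K-1}\sum_k (w_k - \bar w_K)^2}, mean within-replicate
#' variance \eqn{\bar v}, and the fully-synthetic-data variance estimate
#' \eqn{\hat v_K = (1 + 1/K) b - \bar v}. Wherever that estimate is negative
#' the conservative fallback \eqn{(1 + 1/K) b + \bar v} is used instead; the
#' rule applied is recorded per coefficient.
#'
#' @param fits List of `K >= 2` converged [fit_poisson_regression()] results.
#' @return An object of class `rubin_estimate` with fields `mean`, `variance`,
#'   `between`, `within`, `rule` (per-coefficient `"minus"`/`"plus"`), `K`.
#' @export
rubins_rules <- function(fits) {
  K <- length(fits)
  if (K < 2) stop("Rubin's rules need at least K = 2 replicate fits")
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    stop("all replicate fits must have converged")
  }
  W <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  V <- do.call(rbind, lapply(fits, function(f) f$variance))
  w_bar <- colMeans(W)
  b <- apply(W, 2, stats::var)          # divisor K - 1
  v_bar <- colMeans(V)
  v_minus <- (1 + 1 / K) * b - v_bar
  plus <- v_minus < 0
  v_hat <- ifelse(plus, (1 + 1 / K) * b + v_bar, v_minus)
  structure(
    list(
      mean = w_bar,
      variance = v_hat,
      between = b,
      within = v_bar,
      rule = ifelse(plus, "plus", "minus"),
      K = K
    ),
    class = "rubin_estimate"
  )
}

#' Predictive log-likelihood of a weight vector on a test set
#'
#' \eqn{\sum_{(x,y)} [y \ln\lambda - \lambda - \ln(y!)]} with
#' \eqn{\lambda = \exp(w^\top \tilde x)}; for binary outcomes the
#' \eqn{\ln(y!)} term is identically zero. With `normalize = TRUE` (the
#' reporting default) the sum is divided by the test-set size.
#'
#' @param w Weight vector of length `enc$p`.
#' @param test Test tibble with `x1..xd` and `y`.
#' @param enc A [feature_encoding()].
#' @param normalize Divide by the number of test records.
#' @return A single number.
#' @export
predictive_log_likelihood <- function(w, test, enc, normalize = TRUE) {
  if (nrow(test) == 0) stop("test set is empty")
  ll <- sum(log_prob_outcome(test, test$y, w, enc))
  if (normalize) ll / nrow(test) else ll
}

#' Monte-Carlo distribution of predictive log-likelihoods
#'
#' Approximates the distribution of the analysis model's test log-likelihood
#' under parameter uncertainty: weights are drawn from the diagonal Gaussian
#' `N(mean, diag(variance))` summarising the fit (a [rubins_rules()] estimate,
#' or a single [fit_poisson_regression()] whose mean/variance are the MLE and
#' squared standard errors), and each draw is scored on the test set.
#'
#' @param est A `rubin_estimate` or `poisson_fit` object.
#' @param test Test tibble.
#' @param enc A [feature_encoding()].
#' @param n_samples Number of Monte-Carlo draws (conventionally 100).
#' @param seed Integer seed.
#' @param normalize Normalize each log-likelihood by the test-set size.
#' @return A tibble with columns `sample` and `loglik`.
#' @export
sample_loglik_distribution <- function(est, test, enc, n_samples = 100,
                                       seed = 1, normalize = TRUE) {
  if (inherits(est, "rubin_estimate")) {
    mu <- est$mean
    v <- est$variance
  } else if (inherits(est, "poisson_fit")) {
    mu <- est$coefficients
    v <- est$variance
  } else {
    stop("`est` must be a rubin_estimate or poisson_fit")
  }
  v <- ifelse(is.finite(v) & v > 0, v, 0)
  if (any(v < 0)) stop("negative variances in `est`")
  p <- length(mu)
  X <- encode_dataset(test, enc)
  y <- as.numeric(test$y)
  W <- withr::with_seed(derive_seed(seed, "loglik-draws"), {
    matrix(stats::rnorm(p * n_samples), p, n_samples) * sqrt(v) + mu
  })
  eta <- pmin(X %*% W, 30)
  ll <- colSums(y * eta - exp(eta)) - sum(lgamma(y + 1))
  if (normalize) ll <- ll / nrow(X)
  tibble::tibble(sample = seq_len(n_samples), loglik = ll)
}

#' Welch's t-test on pooled mid-ranks
#'
#' Rank-transforms the pooled samples (mid-ranks for ties), then applies
#' Welch's unequal-variance t-test to the two groups of ranks. The rank
#' transform makes the test robust to non-normality and heavy tails in the
#' log-likelihood samples while Welch's statistic accommodates unequal group
#' variances. If every pooled value is tied the test is degenerate and
#' returns `statistic = 0`, `p = 1` by convention.
#'
#' @param a,b Numeric sample vectors (each of length >= 2).
#' @param alternative `"greater"` (one-sided, mean rank of `a` above `b`),
#'   `"less"`, or `"two.sided"`.
#' @return A tibble with `statistic`, `df`, `p_value`, `n_a`, `n_b`,
#'   `alternative`.
#' @export
ranked_welch_test <- function(a, b, alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need at least 2 values")
  r <- rank(c(a, b))  # mid-ranks for ties
  ra <- r[seq_len(na)]
  rb <- r[na + seq_len(nb)]
  va <- stats::var(ra)
  vb <- stats::var(rb)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    stat <- 0
    df <- na + nb - 2
    p <- 1
  } else {
    stat <- (mean(ra) - mean(rb)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- switch(alternative,
                greater = stats::pt(stat, df, lower.tail = FALSE),
                less = stats::pt(stat, df),
                two.sided = 2 * stats::pt(abs(stat), df, lower.tail = FALSE))
    p <- min(p, 1)
  }
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 n_a = na, n_b = nb, alternative = alternative)
}
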