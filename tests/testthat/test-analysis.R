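test_that("intercept-only Poisson MLE has closed form ln(ybar), variance 1/(n ybar)", {
  enc <- feature_encoding(1L)
  ds <- tibble::tibble(x1 = c(0L, 0L), y = c(1L, 3L))
  fit <- fit_poisson_regression(ds, enc)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-9)
  expect_equal(unname(fit$variance), 1 / 4, tolerance = 1e-9)
  # all-zero outcomes: MLE at -Inf, flagged
  ds0 <- tibble::tibble(x1 = rep(0L, 5), y = 0L)
  expect_false(fit_poisson_regression(ds0, enc)$converged)
})

test_that("Newton fit matches the IRLS oracle (stats::glm) in weights and variances", {
  lev <- c(3L, 2L)
  enc <- feature_encoding(lev)
  for (seed in 1:10) {
    ds <- random_cohort(200, lev, seed = seed)
    fit <- fit_poisson_regression(ds, enc)
    X <- encode_dataset(ds, enc)
    oracle <- suppressWarnings(
      glm.fit(X, ds$y, family = poisson(), control = list(epsilon = 1e-12)))
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-6)
    v_oracle <- diag(chol2inv(chol(crossprod(X, X * oracle$fitted.values))))
    expect_equal(unname(fit$variance), v_oracle, tolerance = 1e-6)
  }
})

test_that("rank-deficient designs error with column names; unobserved levels can be dropped", {
  enc <- feature_encoding(3L)
  ds <- tibble::tibble(x1 = rep(c(0L, 1L), 10), y = rep(c(0L, 1L), 10))
  expect_error(fit_poisson_regression(ds, enc), "x1_2")
  fit <- fit_poisson_regression(ds, enc, drop_unobserved = TRUE)
  expect_equal(fit$dropped, "x1_2")
  expect_equal(unname(fit$coefficients["x1_2"]), 0)
  expect_equal(unname(fit$variance["x1_2"]), 0)
})

test_that("Rubin's rules match direct evaluation, including the plus-rule fallback", {
  mk <- function(w, v) {
    structure(list(coefficients = w, variance = v, converged = TRUE),
              class = "poisson_fit")
  }
  est <- rubins_rules(list(mk(0, 0.1), mk(2, 0.1)))
  expect_equal(unname(est$mean), 1)
  expect_equal(unname(est$between), 2)
  expect_equal(unname(est$within), 0.1)
  expect_equal(unname(est$variance), 1.5 * 2 - 0.1)  # minus rule
  expect_equal(unname(est$rule), "minus")
  # identical replicates force b = 0 and the conservative fallback
  est2 <- rubins_rules(list(mk(1, 0.3), mk(1, 0.3), mk(1, 0.3)))
  expect_equal(unname(est2$variance), 0.3)
  expect_equal(unname(est2$rule), "plus")
  # errors
  expect_error(rubins_rules(list(mk(1, 1))), "K = 2")
  bad <- mk(1, 1); bad$converged <- FALSE
  expect_error(rubins_rules(list(mk(1, 1), bad)), "converged")
})

test_that("Rubin combination is permutation-invariant and never negative", {
  mk <- function(w, v) {
    structure(list(coefficients = w, variance = v, converged = TRUE),
              class = "poisson_fit")
  }
  withr::with_seed(13, {
    for (i in 1:50) {
      K <- sample(2:12, 1)
      p <- sample(1:5, 1)
      fits <- lapply(seq_len(K), function(k) mk(rnorm(p), rexp(p)))
      est <- rubins_rules(fits)
      est_perm <- rubins_rules(fits[sample(K)])
      expect_equal(est, est_perm)
      expect_true(all(est$variance >= 0))
      expect_true(all((est$rule == "plus") ==
                        ((1 + 1 / K) * est$between - est$within < 0)))
    }
  })
})

test_that("as K grows the Rubin mean and between-variance approach the sampling law", {
  mk <- function(w, v) {
    structure(list(coefficients = w, variance = v, converged = TRUE),
              class = "poisson_fit")
  }
  mu <- 1.7; s2 <- 0.49
  for (K in c(10, 100, 1000)) {
    fits <- withr::with_seed(K, {
      lapply(seq_len(K), function(k) mk(rnorm(1, mu, sqrt(s2)), 0.01))
    })
    est <- rubins_rules(fits)
    se_mean <- sqrt(s2 / K)
    se_var <- s2 * sqrt(2 / (K - 1))
    expect_lt(abs(unname(est$mean) - mu), 3 * se_mean)
    expect_lt(abs(unname(est$between) - s2), 3 * se_var)
  }
})

test_that("predictive log-likelihood matches per-record summation and is additive", {
  enc <- feature_encoding(1L)
  two <- tibble::tibble(x1 = c(0L, 0L), y = c(0L, 0L))
  expect_equal(predictive_log_likelihood(0, two, enc, normalize = FALSE), -2)
  expect_equal(predictive_log_likelihood(0, two, enc, normalize = TRUE), -1)
  lev <- c(3L, 2L)
  enc2 <- feature_encoding(lev)
  ds <- random_cohort(60, lev, seed = 3)
  w <- withr::with_seed(4, rnorm(enc2$p, 0, 0.5))
  oracle <- sum(vapply(seq_len(nrow(ds)), function(i) {
    lam <- exp(sum(encode_features(unlist(ds[i, 1:2]), enc2) * w))
    ds$y[i] * log(lam) - lam - lgamma(ds$y[i] + 1)
  }, numeric(1)))
  expect_equal(predictive_log_likelihood(w, ds, enc2, normalize = FALSE),
               oracle, tolerance = 1e-12)
  # additivity over a partition (raw mode)
  expect_equal(predictive_log_likelihood(w, ds[1:20, ], enc2, FALSE) +
                 predictive_log_likelihood(w, ds[21:60, ], enc2, FALSE),
               predictive_log_likelihood(w, ds, enc2, FALSE), tolerance = 1e-12)
})

test_that("log-likelihood sampling degenerates correctly as variance shrinks", {
  lev <- c(3L, 2L)
  enc <- feature_encoding(lev)
  ds <- random_cohort(50, lev, seed = 6)
  est <- structure(list(mean = withr::with_seed(7, rnorm(enc$p, 0, 0.3)),
                        variance = rep(0, enc$p), between = rep(0, enc$p),
                        within = rep(0, enc$p), rule = rep("plus", enc$p),
                        K = 5),
                   class = "rubin_estimate")
  point <- predictive_log_likelihood(est$mean, ds, enc)
  s0 <- sample_loglik_distribution(est, ds, enc, n_samples = 20, seed = 1)
  expect_true(all(s0$loglik == point))
  est$variance <- rep(1e-8, enc$p)
  s1 <- sample_loglik_distribution(est, ds, enc, n_samples = 20, seed = 1)
  expect_lt(max(abs(s1$loglik - point)), 1e-2)
})

test_that("ranked Welch test matches the rank-then-t.test oracle and tie conventions", {
  a <- withr::with_seed(8, rnorm(40))
  b <- withr::with_seed(9, rnorm(60, 0.5, 2))
  res <- ranked_welch_test(a, b, "two.sided")
  r <- rank(c(a, b))
  oracle <- t.test(r[1:40], r[41:100], var.equal = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  res_g <- ranked_welch_test(a, b, "greater")
  oracle_g <- t.test(r[1:40], r[41:100], var.equal = FALSE,
                     alternative = "greater")
  expect_equal(res_g$p_value, oracle_g$p.value, tolerance = 1e-10)
  # identical samples: statistic 0, two-sided p = 1
  res_id <- ranked_welch_test(a, a, "two.sided")
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)
  # all values tied: degenerate convention
  res_tie <- ranked_welch_test(rep(1, 5), rep(1, 7), "two.sided")
  expect_equal(res_tie$p_value, 1)
  # complete separation at n = 100 each
  res_sep <- ranked_welch_test(101:200, 1:100, "greater")
  expect_lt(res_sep$p_value, 1e-10)
})
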