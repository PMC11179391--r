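# Tiny experiment configurations: two centers, a 2-component generative
# model, a handful of DP-SGD steps with a fixed noise multiplier. These runs
# exercise the full orchestration (state preparation, combination, Rubin
# pooling, Monte-Carlo evaluation) at shake-out scale; the scientific
# properties at study scale live in the acceptance suite.

tiny_cfg <- function(seed = 9, n_repeats = 2, M = 2, n_pop = 1200,
                     k = 3, perms = 2) {
  experiment_config(
    cohort = cohort_config(n_population = n_pop, n_centers = M,
                           tilt_strength = 0.5, seed = 3),
    train_fraction = 0.5, mixture_components = 2, vi_iterations = 25,
    batch_size = 40, k_replicates = k, n_loglik_samples = 10,
    n_repeats = n_repeats, n_permutations = perms,
    epsilon = 1, delta = 1e-6, seed = seed)
}

state_cache <- new.env(parent = emptyenv())
tiny_state <- function() {
  if (is.null(state_cache$st)) {
    state_cache$cfg <- tiny_cfg()
    state_cache$st <- prepare_study_state(state_cache$cfg, progress = FALSE)
  }
  list(cfg = state_cache$cfg, st = state_cache$st)
}

test_that("study state carries calibrated privacy and per-repeat releases", {
  x <- tiny_state()
  st <- x$st
  expect_length(st$repeats, 2)
  expect_length(st$repeats[[1]], 2)
  for (pp in st$privacy) {
    expect_lte(pp$realized_epsilon, 1)
    expect_gt(pp$realized_epsilon, 0.999)
  }
  expect_equal(st$repeats[[1]][[2]]$bundle$k, 3L)
  # repeats differ in inference randomness, not in the data split
  expect_false(identical(st$repeats[[1]][[1]]$posterior$loc,
                         st$repeats[[2]][[1]]$posterior$loc))
})

test_that("combined-vs-local table has the full design and pooled baseline", {
  x <- tiny_state()
  rt <- run_combined_vs_local(x$cfg, x$st)
  # 2 repeats x 2 centers x 2 conditions x 10 samples + 2 x 10 pooled
  expect_equal(nrow(rt), 2 * 2 * 2 * 10 + 2 * 10)
  expect_setequal(unique(rt$condition), c("local", "combined", "pooled"))
  expect_true(all(is.finite(rt$loglik)))
  counts <- dplyr::count(rt, .data$condition)
  expect_equal(counts$n[counts$condition == "pooled"], 20)
  # replayable bit-for-bit from (config, master seed)
  rt2 <- run_combined_vs_local(x$cfg, x$st)
  expect_identical(rt$loglik, rt2$loglik)
})

test_that("incremental steps interpolate between local-only and fully combined", {
  x <- tiny_state()
  rt <- run_combined_vs_local(x$cfg, x$st)
  ri <- run_incremental(x$cfg, x$st)
  # 2 repeats x 2 centers x 2 perms x 2 steps x 10 samples
  expect_equal(nrow(ri), 2 * 2 * 2 * 2 * 10)
  expect_setequal(unique(ri$step), c(0L, 1L))
  for (r in 1:2) for (m in 1:2) {
    s0 <- ri$loglik[ri$repeat_id == r & ri$center == m & ri$step == 0 &
                      ri$perm_id == 1]
    loc <- rt$loglik[rt$repeat_id == r & !is.na(rt$center) & rt$center == m &
                       rt$condition == "local"]
    expect_identical(s0, loc)
    s_last <- ri$loglik[ri$repeat_id == r & ri$center == m & ri$step == 1 &
                          ri$perm_id == 2]
    comb <- rt$loglik[rt$repeat_id == r & !is.na(rt$center) & rt$center == m &
                        rt$condition == "combined"]
    expect_identical(s_last, comb)
  }
})

test_that("with a single participating center, combined equals local sample for sample", {
  cfg1 <- experiment_config(
    cohort = cohort_config(n_population = 400, n_centers = 1, seed = 3),
    train_fraction = 1, mixture_components = 2, vi_iterations = 15,
    batch_size = 40, k_replicates = 2, n_loglik_samples = 5, n_repeats = 1,
    n_permutations = 1, seed = 4)
  st1 <- prepare_study_state(cfg1, progress = FALSE)
  r1 <- run_combined_vs_local(cfg1, st1)
  expect_identical(r1$loglik[r1$condition == "combined"],
                   r1$loglik[r1$condition == "local"])
})

test_that("size sweep tabulates the focal center across the fraction grid", {
  cfg <- tiny_cfg(seed = 21, n_repeats = 1)
  cfg$size_fractions <- c(0.5, 1)
  rs <- run_size_sweep(cfg, focal_center = 1)
  # |grid| x 2 conditions x repeats x samples for the focal center
  expect_equal(nrow(rs), 2 * 2 * 1 * 10)
  expect_setequal(unique(rs$fraction), c(0.5, 1))
  expect_setequal(unique(rs$center), 1L)
})

test_that("the skew experiment evaluates a population-matched party on the subgroup", {
  x <- tiny_state()
  cfg <- x$cfg
  cfg$skew_fractions <- c(0.25, 1)
  cfg$skew_category <- 1L  # a level certain to exist in the tiny cohort
  rk <- run_skew_experiment(cfg, x$st)
  expect_equal(nrow(rk), 2 * 2 * 2 * 10)
  expect_setequal(unique(rk$condition), c("local", "combined"))
  expect_setequal(unique(rk$keep_fraction), c(0.25, 1))
  expect_true(all(is.finite(rk$loglik)))
})

test_that("significance summaries use ranked Welch with the configured sidedness", {
  x <- tiny_state()
  rt <- run_combined_vs_local(x$cfg, x$st)
  sig <- summarize_significance(rt)
  expect_equal(nrow(sig), 2)
  expect_equal(sig$n_a, rep(2 * 10, 2))  # repeats x samples per condition
  expect_true(all(sig$alternative == "greater"))
  # a condition compared with itself is never significant
  self <- summarize_significance(rt, cond_a = "local", cond_b = "local",
                                 alternative = "two.sided")
  expect_true(all(self$p_value == 1))
  expect_error(summarize_significance(rt, cond_a = "nope"), "not present")
})
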