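test_that("population generation honours the clipped-Poisson outcome law", {
  # single-level feature, intercept-only rate lambda = 1:
  # P(y = 1) = P(Poisson(1) >= 1) = 1 - exp(-1)
  params <- generative_params(1, list(list(1)), 0)
  cfg <- cohort_config(n_population = 100000, level_counts = 1L,
                       true_params = params, n_centers = 1, seed = 4)
  pop <- generate_population(cfg)
  expect_equal(mean(pop$y), 1 - exp(-1), tolerance = 0.01)
  # empty population
  cfg0 <- cohort_config(n_population = 0, level_counts = 1L,
                        true_params = params, n_centers = 1, seed = 4)
  expect_equal(nrow(generate_population(cfg0)), 0)
  # default shape: five features, sixteen components
  cfg5 <- cohort_config(n_population = 200, seed = 1)
  expect_equal(length(cfg5$true_params$mixture_weights), 16)
  pop5 <- generate_population(cfg5)
  expect_named(pop5, c("x1", "x2", "x3", "x4", "x5", "y"))
})

test_that("population and synthetic sampling share the outcome mapping", {
  params <- random_gen_params(2, c(3L, 2L), seed = 31, w_scale = 0.4)
  cfg <- cohort_config(n_population = 500, level_counts = c(3L, 2L),
                       true_params = params, n_centers = 1, seed = 77)
  pop <- generate_population(cfg)
  direct <- sample_synthetic(params, 500,
                             seed = dpcollab::derive_seed(77, "population"))
  expect_identical(pop, direct)
})

test_that("center partition conserves records and tilts the feature distribution", {
  params <- random_gen_params(2, c(4L, 2L), seed = 41)
  cfg <- cohort_config(n_population = 10000, level_counts = c(4L, 2L),
                       true_params = params, n_centers = 4, seed = 8)
  pop <- generate_population(cfg)
  # M = 1: identity (plus center label)
  one <- partition_centers(pop, 1, 2, seed = 1)
  expect_identical(dplyr::select(one[[1]], -dplyr::any_of("center")), pop)
  # conservation and disjointness at tilt 0
  ctr0 <- partition_centers(pop, 2, 0, seed = 2)
  expect_equal(sum(vapply(ctr0, nrow, integer(1))), nrow(pop))
  expect_equal(dplyr::arrange_all(dplyr::bind_rows(lapply(ctr0, function(x) {
    dplyr::select(x, -"center")
  }))), dplyr::arrange_all(pop))
  # tilt 0 keeps local marginals near the population's (TV < 0.05)
  for (ds in ctr0) {
    expect_lt(tv_distance(empirical_marginal(ds, 1, 4),
                          empirical_marginal(pop, 1, 4)), 0.05)
  }
  # strong tilt induces dependence between feature 1 and center assignment
  ctr2 <- partition_centers(pop, 4, 2, seed = 3)
  tab <- table(
    feature = dplyr::bind_rows(ctr2)$x1,
    center = dplyr::bind_rows(ctr2)$center
  )
  stat <- suppressWarnings(chisq.test(tab)$statistic)
  expect_gt(stat, qchisq(0.99, df = (4 - 1) * (4 - 1)))
  # more centers than records errors
  expect_error(partition_centers(pop[1:3, ], 5, 0, seed = 1), "more centers")
})

test_that("subsampling follows the floor rule and is a no-op at fraction 1", {
  ds <- random_cohort(10, c(3L, 2L), seed = 5)
  expect_identical(subsample_dataset(ds, 1, seed = 1), ds)
  expect_equal(nrow(subsample_dataset(ds, 0.25, seed = 1)), 2)  # floor(2.5)
  expect_error(subsample_dataset(ds, 0, seed = 1), "fraction")
  expect_error(subsample_dataset(ds, 1.2, seed = 1), "fraction")
  # determinism and containment
  s1 <- subsample_dataset(ds, 0.5, seed = 9)
  expect_identical(s1, subsample_dataset(ds, 0.5, seed = 9))
})

test_that("marginal-skew injection depletes exactly the targeted cell", {
  # constructed fixture: 40 records in the target cell, 60 elsewhere
  cell <- tibble::tibble(x1 = 1L, x2 = rep(0:1, 20), y = 1L)
  rest <- tibble::tibble(x1 = rep(c(0L, 1L, 2L), each = 20),
                         x2 = 1L, y = rep(c(1L, 0L, 1L), each = 20))
  ds <- dplyr::bind_rows(cell, rest)
  out <- inject_marginal_skew(ds, 1, 1L, 1L, 0.25, seed = 3)
  # exactly 10 of the 40 target-cell records remain (plus the 20 untargeted
  # (x1 = 1, y = 1) records coming from `rest`... none: rest has y != 1 there)
  expect_equal(sum(out$x1 == 1L & out$y == 1L), 10)
  # every other two-way cell is untouched
  for (xv in 0:2) for (yv in 0:1) {
    if (xv == 1 && yv == 1) next
    expect_equal(sum(out$x1 == xv & out$y == yv), sum(ds$x1 == xv & ds$y == yv))
  }
  # round-half-up keeps small cells alive: 3 records at 10% -> 0.3 -> 0
  # but 5 records at 10% -> 0.5 -> 1
  small <- tibble::tibble(x1 = rep(1L, 5), x2 = 0L, y = 1L)
  kept <- inject_marginal_skew(small, 1, 1L, 1L, 0.10, seed = 1)
  expect_equal(nrow(kept), 1)
  # identity and empty-cell behaviour
  expect_identical(inject_marginal_skew(ds, 1, 1L, 1L, 1, seed = 1), ds)
  expect_warning(out2 <- inject_marginal_skew(ds, 1, 2L, 0L, 0.5, seed = 1),
                 "empty")
  expect_identical(out2, ds)
})

test_that("train/test split is per-center, disjoint, and reproducible", {
  params <- random_gen_params(2, c(3L, 2L), seed = 51)
  centers <- lapply(1:3, function(m) {
    d <- random_cohort(100, c(3L, 2L), seed = m)
    d$center <- m
    d
  })
  sp <- split_train_test(centers, 0.8, seed = 6)
  expect_equal(vapply(sp$train, nrow, integer(1)), rep(80L, 3))
  expect_equal(nrow(sp$test), 3 * 20)
  # global test is the union of the per-center complements
  for (m in 1:3) {
    expect_equal(nrow(sp$train[[m]]) + sum(sp$test$center == m), 100)
  }
  sp2 <- split_train_test(centers, 0.8, seed = 6)
  expect_identical(sp, sp2)
  expect_error(split_train_test(list(centers[[1]][0, ]), 0.8, 1), "empty")
  expect_error(split_train_test(centers, 1, 1), "ratio")
})
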