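#' Configuration for the synthetic multi-center cohort generator
#'
#' Describes a ground-truth population with known generative parameters and
#' how it is divided into heterogeneous centers. The defaults emulate a
#' multi-center SARS-CoV-2 testing cohort: five categorical socio-demographic
#' features, a binary test outcome following a log-linear rate model with a
#' population positivity rate around 13%, eight centers of a few thousand
#' records each, and a moderate center-level covariate shift
#' (`tilt_strength = 1`) so that local feature distributions deviate from the
#' population (`Pr[x | center] != Pr[x]`).
#'
#' @param n_population Number of records in the ground-truth population.
#' @param level_counts Integer vector, categories per feature (codes 0-based).
#' @param true_params A [generative_params()] object used as ground truth;
#'   defaults to [default_true_params()] on `level_counts`.
#' @param n_centers Number of disjoint centers `M >= 1`.
#' @param tilt_strength Non-negative scale of the center-assignment shift; 0
#'   gives uniform multinomial assignment.
#' @param seed Integer seed for population generation and partitioning.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_population = 20000,
                          level_counts = c(4L, 4L, 3L, 3L, 2L),
                          true_params = default_true_params(level_counts),
                          n_centers = 8,
                          tilt_strength = 1,
                          seed = 1) {
  stopifnot(n_population >= 0, n_centers >= 1, tilt_strength >= 0)
  if (!identical(as.integer(level_counts),
                 as.integer(gp_levels(true_params)))) {
    stop("`level_counts` must match the level counts of `true_params`")
  }
  structure(
    list(
      n_population = as.integer(n_population),
      level_counts = as.integer(level_counts),
      true_params = true_params,
      n_centers = as.integer(n_centers),
      tilt_strength = tilt_strength,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default ground-truth parameters for the simulated cohort
#'
#' Builds a fixed, reproducible `gen_params` object: 16 mixture components
#' whose per-feature categoricals are Dirichlet draws centred on target
#' population marginals (concentration 6, so components differ visibly), and a
#' fixed regression weight vector. The first feature plays the role of an
#' ethnicity-like covariate with a dominant majority category and an 8%
#' minority category (code 3) whose positivity rate is elevated
#' (weight +0.8 on the log scale); remaining features carry moderate effects.
#' The intercept `log(0.10)` puts the marginal positivity rate near 13%, so
#' the Poisson rates stay well below 1 and the clip-to-binary outcome mapping
#' almost never truncates.
#'
#' @param level_counts Integer vector of categories per feature; the default
#'   weight vector is defined for `c(4, 4, 3, 3, 2)` and other shapes get
#'   weights drawn once from the construction seed.
#' @param components Number of mixture components (default 16).
#' @param construction_seed Seed fixing the component draws.
#' @return A [generative_params()] object.
#' @export
default_true_params <- function(level_counts = c(4L, 4L, 3L, 3L, 2L),
                                components = 16,
                                construction_seed = 760321) {
  level_counts <- as.integer(level_counts)
  d <- length(level_counts)
  marginals <- lapply(seq_len(d), function(j) {
    L <- level_counts[j]
    if (j == 1 && L == 4L) {
      c(0.70, 0.12, 0.10, 0.08)   # majority + minority-group structure
    } else {
      m <- 0.55 * 0.6^(seq_len(L) - 1)
      m / sum(m)
    }
  })
  withr::with_seed(construction_seed, {
    pi_ <- rgamma(components, 4)
    pi_ <- pi_ / sum(pi_)
    theta <- lapply(seq_len(components), function(r) {
      lapply(seq_len(d), function(j) {
        g <- rgamma(level_counts[j], 6 * marginals[[j]])
        g / sum(g)
      })
    })
    p <- 1L + sum(level_counts - 1L)
    if (identical(level_counts, c(4L, 4L, 3L, 3L, 2L))) {
      w <- c(log(0.10),
             0.25, 0.45, 0.80,    # feature 1; code 3 = elevated-rate minority
             -0.20, 0.35, 0.15,   # feature 2
             0.30, -0.25,         # feature 3
             0.20, -0.30,         # feature 4
             0.40)                # feature 5
    } else {
      w <- c(log(0.10), round(stats::runif(p - 1L, -0.5, 0.8), 2))
    }
    generative_params(pi_, theta, w)
  })
}

#' Generate a ground-truth population
#'
#' Draws `n_population` i.i.d. records from the configured generative model:
#' mixture component, features given component, and a Poisson outcome
#' \eqn{y \sim \mathrm{Poisson}(\exp(w^\top \tilde x))} clipped to `{0, 1}`
#' (the same mapping used by [sample_synthetic()]).
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble with columns `x1..xd`, `y`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sample_synthetic(config$true_params, config$n_population,
                   seed = derive_seed(config$seed, "population"))
}

#' Partition a population into heterogeneous centers
#'
#' Assigns every record to one of `M` centers by a multinomial draw whose
#' probabilities are tilted by center-specific affinities for the first
#' feature's categories: each center `m` gets a log-affinity vector
#' `a_m ~ N(0, tilt_strength^2)` per category of feature 1, and record `i`
#' joins center `m` with probability `softmax_m(a_m[x_i1])`. With
#' `tilt_strength = 0` assignment is uniform; larger values give centers whose
#' local feature distributions shift away from the population's. The output
#' datasets are disjoint and their union is the input.
#'
#' @param data Population tibble (`x1..xd`, `y`).
#' @param n_centers Number of centers `M >= 1` (must not exceed `nrow(data)`).
#' @param tilt_strength Non-negative shift magnitude.
#' @param seed Integer seed.
#' @return A list of `M` cohort tibbles, each with a `center` column.
#' @export
partition_centers <- function(data, n_centers, tilt_strength, seed) {
  n <- nrow(data)
  M <- as.integer(n_centers)
  stopifnot(M >= 1, tilt_strength >= 0)
  if (M > n) stop("more centers (", M, ") than records (", n, ")")
  if (M == 1L) {
    out <- data
    out$center <- 1L
    return(list(out))
  }
  L1 <- max(data$x1) + 1L
  assign <- withr::with_seed(derive_seed(seed, "partition"), {
    aff <- matrix(stats::rnorm(M * L1, 0, tilt_strength), M, L1)
    a <- integer(n)
    for (l in seq_len(L1) - 1L) {
      idx <- which(data$x1 == l)
      if (length(idx) == 0) next
      pr <- exp(aff[, l + 1L] - max(aff[, l + 1L]))
      a[idx] <- sample.int(M, length(idx), replace = TRUE, prob = pr)
    }
    a
  })
  lapply(seq_len(M), function(m) {
    out <- data[assign == m, , drop = FALSE]
    out$center <- m
    out
  })
}

#' Uniformly subsample a dataset without replacement
#'
#' Keeps `floor(fraction * n)` records chosen uniformly at random; the floor
#' rule makes the size deterministic and never exceeds the requested fraction.
#'
#' @param data Cohort tibble.
#' @param fraction Sampling fraction in `(0, 1]`; 1 returns the data unchanged.
#' @param seed Integer seed.
#' @return The subsampled tibble (original row order preserved).
#' @export
subsample_dataset <- function(data, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]")
  }
  if (fraction == 1) return(data)
  n <- nrow(data)
  keep <- floor(fraction * n)
  idx <- withr::with_seed(derive_seed(seed, "subsample"),
                          sort(sample.int(n, keep)))
  data[idx, , drop = FALSE]
}

#' Deplete one two-way marginal cell of a dataset
#'
#' Subsamples the records in the cell `(feature == category, y == outcome_value)`
#' to `round(keep_fraction * cell_count)` (round-half-up, so 10% of small cells
#' stays nonzero), leaving every other record untouched. This injects a
#' controlled skew into the joint distribution of one covariate and the
#' outcome, emulating, e.g., under-reporting of positive tests within a
#' minority group.
#'
#' @param data Cohort tibble.
#' @param feature Feature index (1-based column among `x1..xd`).
#' @param category Category code (0-based) of the targeted cell.
#' @param outcome_value Outcome value of the targeted cell, 0 or 1.
#' @param keep_fraction Fraction of the cell to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return The skewed tibble (original row order preserved). If the target
#'   cell is empty, warns and returns `data` unchanged.
#' @export
inject_marginal_skew <- function(data, feature, category, outcome_value,
                                 keep_fraction, seed) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must lie in (0, 1]")
  }
  col <- paste0("x", feature)
  cell <- which(data[[col]] == category & data$y == outcome_value)
  if (length(cell) == 0) {
    warning("target cell (x", feature, " = ", category, ", y = ",
            outcome_value, ") is empty; returning data unchanged")
    return(data)
  }
  if (keep_fraction == 1) return(data)
  keep_n <- floor(keep_fraction * length(cell) + 0.5)  # round half up
  kept <- withr::with_seed(derive_seed(seed, "skew"),
                           sort(sample(cell, keep_n)))
  drop_idx <- setdiff(cell, kept)
  if (length(drop_idx) == 0) return(data)
  data[-drop_idx, , drop = FALSE]
}

#' Split centers into training sets and a global test set
#'
#' Splits each center uniformly at random into a training part (fraction
#' `ratio`, size `floor(ratio * n)`) and a held-out part; the global test set
#' is the union of the per-center held-out parts and stands in for an unbiased
#' sample of the whole population.
#'
#' @param centers List of cohort tibbles (as from [partition_centers()]).
#' @param ratio Training fraction in `(0, 1)`; the conventional choice is 0.8.
#' @param seed Integer seed; the same seed reproduces the identical split.
#' @return A list with `train` (list of per-center training tibbles) and
#'   `test` (one tibble, the global test set).
#' @export
split_train_test <- function(centers, ratio, seed) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must lie in (0, 1)")
  }
  train <- vector("list", length(centers))
  test <- vector("list", length(centers))
  for (m in seq_along(centers)) {
    n <- nrow(centers[[m]])
    if (n == 0) stop("center ", m, " is empty")
    idx <- withr::with_seed(derive_seed(seed, "split", m),
                            sort(sample.int(n, floor(ratio * n))))
    train[[m]] <- centers[[m]][idx, , drop = FALSE]
    test[[m]] <- centers[[m]][-idx, , drop = FALSE]
  }
  list(train = train, test = dplyr::bind_rows(test))
}
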