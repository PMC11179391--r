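#' Configuration of a collaborative-learning experiment
#'
#' Bundles the cohort design, privacy target, inference settings and protocol
#' constants of the collaborative data-sharing experiments. Defaults follow
#' the study conventions: privacy target `(epsilon, delta) = (1, 1e-6)`,
#' local training data subsampled to 10% of its initial size, `K = 100`
#' synthetic replicates per party, 100 Monte-Carlo log-likelihood draws per
#' fitted model, 10 experiment repeats (fresh inference randomness, fixed
#' cohort split), 100 random orderings in the incremental experiment, a
#' `{10, 20, 50, 100}%` local-size sweep, and a `{10, 25, 50, 75}%`
#' keep-fraction grid for the marginal-skew experiment.
#'
#' @param cohort A [cohort_config()].
#' @param train_fraction Fraction each center's training data is subsampled
#'   to before any fitting (in `(0, 1]`).
#' @param epsilon,delta Privacy target per party.
#' @param clip_norm DP-SGD clipping norm.
#' @param mixture_components Components of each party's generative model.
#' @param vi_iterations DP-SGD iterations per fit.
#' @param batch_size Target expected batch size; a party with `n` local
#'   records uses subsampling ratio `q = min(1, batch_size / n)`.
#' @param learn_rate Adam step size.
#' @param k_replicates Synthetic replicates released per party (`K`).
#' @param n_loglik_samples Monte-Carlo draws per log-likelihood distribution.
#' @param n_repeats Experiment repeats.
#' @param n_permutations Orderings in the incremental experiment.
#' @param size_fractions Local-size sweep grid.
#' @param skew_fractions Keep-fraction grid of the skew experiment.
#' @param skew_feature,skew_category,skew_outcome The depleted two-way cell:
#'   feature index, category code, outcome value. Defaults target the
#'   minority category of the ethnicity-like first feature and positive
#'   outcomes.
#' @param test_ratio Held-out fraction per center (train ratio is
#'   `1 - test_ratio`).
#' @param seed Master seed for all inference/evaluation randomness.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              train_fraction = 0.10,
                              epsilon = 1, delta = 1e-6, clip_norm = 2,
                              mixture_components = 16,
                              vi_iterations = 1500,
                              batch_size = 100,
                              learn_rate = 0.01,
                              k_replicates = 100,
                              n_loglik_samples = 100,
                              n_repeats = 10,
                              n_permutations = 100,
                              size_fractions = c(0.10, 0.20, 0.50, 1.00),
                              skew_fractions = c(0.10, 0.25, 0.50, 0.75),
                              skew_feature = 1, skew_category = 3,
                              skew_outcome = 1,
                              test_ratio = 0.2,
                              seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"),
            train_fraction > 0, train_fraction <= 1,
            k_replicates >= 1, n_loglik_samples >= 1, n_repeats >= 1,
            n_permutations >= 1, test_ratio > 0, test_ratio < 1,
            all(size_fractions > 0 & size_fractions <= 1),
            all(skew_fractions > 0 & skew_fractions <= 1))
  structure(
    list(cohort = cohort, train_fraction = train_fraction,
         epsilon = epsilon, delta = delta, clip_norm = clip_norm,
         mixture_components = as.integer(mixture_components),
         vi_iterations = as.integer(vi_iterations),
         batch_size = batch_size, learn_rate = learn_rate,
         k_replicates = as.integer(k_replicates),
         n_loglik_samples = as.integer(n_loglik_samples),
         n_repeats = as.integer(n_repeats),
         n_permutations = as.integer(n_permutations),
         size_fractions = size_fractions, skew_fractions = skew_fractions,
         skew_feature = as.integer(skew_feature),
         skew_category = as.integer(skew_category),
         skew_outcome = as.integer(skew_outcome),
         test_ratio = test_ratio, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Prepare the shared pipeline state of an experiment
#'
#' Runs the stages every experiment reuses: simulate the cohort, partition it
#' into centers, make the fixed train/test split, subsample each center's
#' training data, calibrate each party's noise multiplier, and — per repeat
#' and per center — fit the DP generative model and release its K synthetic
#' replicates. The cohort and split are fixed across repeats; only the
#' inference and release randomness varies, one named stream per (repeat,
#' center). Passing the returned state to several experiment drivers lets
#' them share the expensive fits consistently.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-stage progress messages.
#' @return An object of class `study_state`.
#' @export
prepare_study_state <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (progress) message(...)
  cc <- cfg$cohort
  pop <- generate_population(cc)
  centers <- partition_centers(pop, cc$n_centers, cc$tilt_strength, cc$seed)
  sp <- split_train_test(centers, 1 - cfg$test_ratio, cc$seed)
  M <- cc$n_centers
  train <- lapply(seq_len(M), function(m) {
    subsample_dataset(sp$train[[m]], cfg$train_fraction,
                      derive_seed(cc$seed, "train-subsample", m))
  })
  enc <- feature_encoding(cc$level_counts)
  say("cohort ready: ", M, " centers, train sizes ",
      paste(vapply(train, nrow, integer(1)), collapse = "/"),
      ", test ", nrow(sp$test))
  sigma_cache <- new.env(parent = emptyenv())
  pps <- lapply(seq_len(M), function(m) {
    n_m <- nrow(train[[m]])
    if (n_m < 2) stop("center ", m, " has fewer than 2 training records")
    q <- min(1, cfg$batch_size / n_m)
    key <- format(q, digits = 12)
    if (is.null(sigma_cache[[key]])) {
      say("calibrating noise for q = ", signif(q, 4))
      sigma_cache[[key]] <- calibrate_noise(cfg$epsilon, cfg$delta, q,
                                            cfg$vi_iterations)
    }
    pp <- privacy_params(cfg$epsilon, cfg$delta, cfg$clip_norm,
                         sigma_cache[[key]], q, cfg$vi_iterations)
    calibrate_privacy(pp)
  })
  fits <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    fits[[r]] <- lapply(seq_len(M), function(m) {
      say("repeat ", r, ": fitting DP generative model for center ", m)
      post <- fit_dpvi(train[[m]], cc$level_counts, pps[[m]],
                       mixture_components = cfg$mixture_components,
                       learn_rate = cfg$learn_rate,
                       seed = derive_seed(cfg$seed, "dpvi", r, m))
      bundle <- release_synthetic_sets(post, k = cfg$k_replicates,
                                       n = nrow(train[[m]]), party = m,
                                       seed = derive_seed(cfg$seed, "release", r, m))
      list(posterior = post, bundle = bundle)
    })
  }
  structure(
    list(config = cfg, centers = centers, train = train, test = sp$test,
         enc = enc, privacy = pps, repeats = fits),
    class = "study_state"
  )
}

#' @export
print.study_state <- function(x, ...) {
  cat("<study_state>", length(x$train), "centers,",
      length(x$repeats), "repeats, K =", x$config$k_replicates, "\n")
  invisible(x)
}

result_table <- function(rows, experiment) {
  out <- dplyr::bind_rows(rows)
  attr(out, "experiment") <- experiment
  class(out) <- c("dpcollab_result", class(out))
  out
}

# Rubin-combined fit over the k combined sets of one recipient.
combined_rubin <- function(local_train, bundles, k, enc, exclude_party = NULL) {
  sets <- assemble_combined_sets(local_train, bundles, k,
                                 exclude_party = exclude_party)
  fits <- lapply(sets, fit_poisson_regression, enc = enc,
                 drop_unobserved = TRUE)
  rubins_rules(fits)
}

#' Combined-versus-local experiment
#'
#' For every repeat and every center: fit the analysis model on the center's
#' local training data alone, and on the K combined sets (local data plus the
#' k-th synthetic replicate of every other center) pooled with Rubin's rules;
#' sample the Monte-Carlo predictive log-likelihood distribution of both on
#' the global test set. A privacy-agnostic `pooled` baseline fit on the union
#' of all centers' local training data is included for reference. Local and
#' combined draws of the same (repeat, center) share a random stream, so with
#' a single participating center the two conditions coincide sample for
#' sample.
#'
#' @param cfg An [experiment_config()].
#' @param state Optional precomputed [prepare_study_state()] for `cfg`.
#' @return A long-format result tibble: `experiment`, `center`, `condition`
#'   (`"local"`, `"combined"`, `"pooled"`), `repeat_id`, `sample`, `loglik`
#'   (normalized by test-set size).
#' @export
run_combined_vs_local <- function(cfg, state = NULL) {
  state <- state %||% prepare_study_state(cfg)
  M <- length(state$train)
  enc <- state$enc
  test <- state$test
  local_fits <- lapply(state$train, fit_poisson_regression, enc = enc,
                       drop_unobserved = TRUE)
  pooled_fit <- fit_poisson_regression(dplyr::bind_rows(state$train), enc,
                                       drop_unobserved = TRUE)
  rows <- list()
  for (r in seq_len(cfg$n_repeats)) {
    bundles <- lapply(state$repeats[[r]], `[[`, "bundle")
    for (m in seq_len(M)) {
      ll_seed <- derive_seed(cfg$seed, "loglik", r, m)
      ll_local <- sample_loglik_distribution(local_fits[[m]], test, enc,
                                             cfg$n_loglik_samples, ll_seed)
      est <- combined_rubin(state$train[[m]], bundles, cfg$k_replicates, enc,
                            exclude_party = m)
      ll_comb <- sample_loglik_distribution(est, test, enc,
                                            cfg$n_loglik_samples, ll_seed)
      rows <- c(rows, list(
        tibble::tibble(center = m, condition = "local", repeat_id = r,
                       sample = ll_local$sample, loglik = ll_local$loglik),
        tibble::tibble(center = m, condition = "combined", repeat_id = r,
                       sample = ll_comb$sample, loglik = ll_comb$loglik)))
    }
    ll_pool <- sample_loglik_distribution(pooled_fit, test, enc,
                                          cfg$n_loglik_samples,
                                          derive_seed(cfg$seed, "loglik-pooled", r))
    rows <- c(rows, list(
      tibble::tibble(center = NA_integer_, condition = "pooled", repeat_id = r,
                     sample = ll_pool$sample, loglik = ll_pool$loglik)))
  }
  out <- result_table(rows, "combined_vs_local")
  out$experiment <- "combined_vs_local"
  dplyr::relocate(out, "experiment")
}

#' Incremental data-sharing experiment
#'
#' From the perspective of each center, synthetic data from the other centers
#' is added one party at a time in a random order, and the Rubin-combined
#' analysis model is re-evaluated after every step (step 0 is the local-only
#' model). Combination is replicate-aligned: at every step the k-th combined
#' set uses replicate k of each party added so far, so K stays fixed along
#' the path and the final step coincides with the full combined condition of
#' [run_combined_vs_local()] under shared seeds. Repeated for
#' `n_permutations` random orderings per repeat; fits are cached by the set
#' of included parties, which the result depends on.
#'
#' @inheritParams run_combined_vs_local
#' @param focal_centers Centers to run the experiment for (default: all).
#' @return A result tibble with columns `experiment`, `center`, `perm_id`,
#'   `step` (number of other parties included), `repeat_id`, `sample`,
#'   `loglik`.
#' @export
run_incremental <- function(cfg, state = NULL, focal_centers = NULL) {
  state <- state %||% prepare_study_state(cfg)
  M <- length(state$train)
  focal_centers <- focal_centers %||% seq_len(M)
  enc <- state$enc
  test <- state$test
  local_fits <- lapply(state$train, fit_poisson_regression, enc = enc,
                       drop_unobserved = TRUE)
  rows <- list()
  for (r in seq_len(cfg$n_repeats)) {
    bundles <- lapply(state$repeats[[r]], `[[`, "bundle")
    cache <- new.env(parent = emptyenv())
    for (m in focal_centers) {
      ll_seed <- derive_seed(cfg$seed, "loglik", r, m)
      ll0 <- sample_loglik_distribution(local_fits[[m]], test, enc,
                                        cfg$n_loglik_samples, ll_seed)
      others <- setdiff(seq_len(M), m)
      for (p in seq_len(cfg$n_permutations)) {
        ord <- withr::with_seed(derive_seed(cfg$seed, "perm", r, m, p),
                                others[sample.int(length(others))])
        rows <- c(rows, list(
          tibble::tibble(center = m, perm_id = p, step = 0L, repeat_id = r,
                         sample = ll0$sample, loglik = ll0$loglik)))
        for (s in seq_along(ord)) {
          included <- sort(ord[seq_len(s)])
          key <- paste(m, paste(included, collapse = "."), sep = "|")
          if (is.null(cache[[key]])) {
            est <- combined_rubin(state$train[[m]], bundles[included],
                                  cfg$k_replicates, enc)
            cache[[key]] <- sample_loglik_distribution(
              est, test, enc, cfg$n_loglik_samples, ll_seed)
          }
          ll <- cache[[key]]
          rows <- c(rows, list(
            tibble::tibble(center = m, perm_id = p, step = s, repeat_id = r,
                           sample = ll$sample, loglik = ll$loglik)))
        }
      }
    }
  }
  out <- result_table(rows, "incremental")
  out$experiment <- "incremental"
  dplyr::relocate(out, "experiment")
}

#' Local-data size sweep
#'
#' Repeats the combined-versus-local experiment with every center's training
#' data subsampled to each fraction of the sweep grid, tabulating one focal
#' center's local and combined conditions per fraction. Each fraction is a
#' full pipeline run (generative fits included), since the parties' synthetic
#' data must be regenerated from the smaller local sets.
#'
#' @inheritParams run_combined_vs_local
#' @param focal_center The center whose results are tabulated.
#' @return A result tibble like [run_combined_vs_local()]'s with an
#'   additional `fraction` column, restricted to the focal center.
#' @export
run_size_sweep <- function(cfg, focal_center = 1) {
  rows <- lapply(cfg$size_fractions, function(f) {
    cfg_f <- cfg
    cfg_f$train_fraction <- f
    rt <- run_combined_vs_local(cfg_f, state = prepare_study_state(cfg_f))
    rt <- rt[!is.na(rt$center) & rt$center == focal_center, ]
    rt$fraction <- f
    rt
  })
  out <- result_table(rows, "size_sweep")
  out$experiment <- "size_sweep"
  dplyr::relocate(out, "experiment")
}

#' Local-skew correction experiment
#'
#' Builds an artificial population-matched party from half of the global test
#' set (the other half remains for evaluation), depletes its
#' `(skew_feature = skew_category, y = skew_outcome)` two-way-marginal cell
#' to each keep fraction of the grid, and compares the skewed party's
#' local-only analysis model against combining its skewed data with every
#' center's synthetic replicates. Log-likelihoods are evaluated on the
#' skewed category's subgroup of the evaluation half, so the result measures
#' how well the model serves the underrepresented group.
#'
#' @inheritParams run_combined_vs_local
#' @return A result tibble with columns `experiment`, `keep_fraction`,
#'   `condition` (`"local"`, `"combined"`), `repeat_id`, `sample`, `loglik`.
#' @export
run_skew_experiment <- function(cfg, state = NULL) {
  state <- state %||% prepare_study_state(cfg)
  enc <- state$enc
  test <- state$test
  n_test <- nrow(test)
  half <- withr::with_seed(derive_seed(cfg$seed, "skew-split"),
                           sort(sample.int(n_test, floor(n_test / 2))))
  party <- test[half, , drop = FALSE]
  eval_half <- test[-half, , drop = FALSE]
  subgroup <- eval_half[eval_half[[paste0("x", cfg$skew_feature)]] ==
                          cfg$skew_category, , drop = FALSE]
  if (nrow(subgroup) == 0) {
    stop("evaluation subgroup (x", cfg$skew_feature, " = ", cfg$skew_category,
         ") is empty")
  }
  rows <- list()
  for (fi in seq_along(cfg$skew_fractions)) {
    keep <- cfg$skew_fractions[fi]
    skewed <- inject_marginal_skew(party, cfg$skew_feature, cfg$skew_category,
                                   cfg$skew_outcome, keep,
                                   derive_seed(cfg$seed, "skew-cell", fi))
    local_fit <- fit_poisson_regression(skewed, enc, drop_unobserved = TRUE)
    for (r in seq_len(cfg$n_repeats)) {
      bundles <- lapply(state$repeats[[r]], `[[`, "bundle")
      ll_seed <- derive_seed(cfg$seed, "loglik-skew", r, fi)
      ll_local <- sample_loglik_distribution(local_fit, subgroup, enc,
                                             cfg$n_loglik_samples, ll_seed)
      est <- combined_rubin(skewed, bundles, cfg$k_replicates, enc)
      ll_comb <- sample_loglik_distribution(est, subgroup, enc,
                                            cfg$n_loglik_samples, ll_seed)
      rows <- c(rows, list(
        tibble::tibble(keep_fraction = keep, condition = "local",
                       repeat_id = r, sample = ll_local$sample,
                       loglik = ll_local$loglik),
        tibble::tibble(keep_fraction = keep, condition = "combined",
                       repeat_id = r, sample = ll_comb$sample,
                       loglik = ll_comb$loglik)))
    }
  }
  out <- result_table(rows, "skew")
  out$experiment <- "skew"
  dplyr::relocate(out, "experiment")
}

#' Ranked Welch significance summary of a result table
#'
#' Compares two conditions' log-likelihood samples within each group of the
#' result table (by default per center) with [ranked_welch_test()]. The
#' convention follows the study design: one-sided tests for
#' combined-versus-local improvements, two-sided for the skew comparisons.
#'
#' @param result A result tibble from one of the `run_*` experiment drivers.
#' @param cond_a,cond_b Condition labels to compare (`cond_a` above `cond_b`
#'   under `alternative = "greater"`).
#' @param by Grouping columns (e.g. `"center"`, `"keep_fraction"`); defaults
#'   to `"center"` when present, otherwise `"keep_fraction"`.
#' @param alternative Passed to [ranked_welch_test()].
#' @return A tibble with one row per group: grouping columns, `statistic`,
#'   `df`, `p_value`, `n_a`, `n_b`, `alternative`.
#' @export
summarize_significance <- function(result, cond_a = "combined",
                                   cond_b = "local", by = NULL,
                                   alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  by <- by %||% intersect(c("center", "keep_fraction"), names(result))[1]
  if (is.na(by) || !all(by %in% names(result))) {
    stop("grouping column(s) not found in `result`")
  }
  present <- unique(result$condition)
  for (cnd in c(cond_a, cond_b)) {
    if (!cnd %in% present) stop("condition '", cnd, "' not present in `result`")
  }
  groups <- dplyr::distinct(result[result$condition %in% c(cond_a, cond_b),
                                   by, drop = FALSE])
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, , drop = FALSE]
    sel <- rep(TRUE, nrow(result))
    for (col in by) sel <- sel & result[[col]] == g[[col]]
    a <- result$loglik[sel & result$condition == cond_a]
    b <- result$loglik[sel & result$condition == cond_b]
    dplyr::bind_cols(g, ranked_welch_test(a, b, alternative))
  })
}
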