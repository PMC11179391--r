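#' Read and write cohort datasets as CSV
#'
#' The on-disk exchange format for cohorts and synthetic replicates: a UTF-8
#' comma-separated file with a header row, integer feature columns `x1..xd`
#' (0-based category codes), a binary outcome column `y`, and an optional
#' integer `center` column. Internal provenance columns (names starting with
#' a dot) are stripped on export.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @param level_counts Optional; when supplied, codes are validated against it
#'   on read.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()` returns
#'   `path` invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  keep <- !startsWith(names(data), ".")
  readr::write_csv(data[keep], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, level_counts = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_integer()))
  xcols <- grep("^x[0-9]+$", names(out), value = TRUE)
  if (length(xcols) == 0 || !"y" %in% names(out)) {
    stop("cohort CSV must have feature columns x1..xd and an outcome column y")
  }
  if (!all(out$y %in% c(0L, 1L))) stop("outcome column y must be binary 0/1")
  if (!is.null(level_counts)) {
    for (j in seq_along(level_counts)) {
      v <- out[[paste0("x", j)]]
      if (any(v < 0L | v >= level_counts[j])) {
        stop("feature x", j, " has codes outside [0, ", level_counts[j], ")")
      }
    }
  }
  tibble::as_tibble(out)
}

#' Serialize generative-model parameters to JSON
#'
#' @param params A [generative_params()] object.
#' @param path File path.
#' @return `read_gen_params()` returns a [generative_params()];
#'   `write_gen_params()` returns `path` invisibly.
#' @export
write_gen_params <- function(params, path) {
  stopifnot(inherits(params, "gen_params"))
  jsonlite::write_json(
    list(mixture_weights = params$mixture_weights,
         component_categoricals = params$component_categoricals,
         regression_weights = params$regression_weights),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_gen_params
#' @export
read_gen_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  theta <- lapply(x$component_categoricals, function(comp) {
    lapply(comp, as.numeric)
  })
  generative_params(x$mixture_weights, theta, x$regression_weights)
}

#' Serialize a fitted variational posterior to JSON
#'
#' Stores the mean-field locations and log-scales, the transform layout
#' (components, level counts), and the privacy ledger (sigma, q, T, delta,
#' realized epsilon) — everything needed to re-draw synthetic data or audit
#' the privacy claim.
#'
#' @param post A `dpvi_posterior`.
#' @param path File path.
#' @return `read_posterior()` returns a `dpvi_posterior`;
#'   `write_posterior()` returns `path` invisibly.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "dpvi_posterior"))
  pp <- post$privacy
  jsonlite::write_json(
    list(loc = post$loc, log_scale = post$log_scale,
         mixture_components = post$spec$R,
         level_counts = post$spec$level_counts,
         w_prior_scale = post$w_prior_scale,
         n_train = post$n_train, seed = post$seed,
         privacy = list(epsilon = pp$epsilon, delta = pp$delta,
                        clip_norm = pp$clip_norm,
                        noise_multiplier = pp$noise_multiplier,
                        subsampling_ratio = pp$subsampling_ratio,
                        iterations = pp$iterations,
                        realized_epsilon = pp$realized_epsilon)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- privacy_params(x$privacy$epsilon, x$privacy$delta, x$privacy$clip_norm,
                       x$privacy$noise_multiplier, x$privacy$subsampling_ratio,
                       x$privacy$iterations)
  pp$realized_epsilon <- x$privacy$realized_epsilon
  structure(
    list(loc = as.numeric(x$loc), log_scale = as.numeric(x$log_scale),
         spec = vp_spec(x$mixture_components, x$level_counts),
         privacy = pp, w_prior_scale = x$w_prior_scale,
         learn_rate = NA_real_, n_train = x$n_train, seed = x$seed,
         trace = NULL),
    class = "dpvi_posterior"
  )
}

#' Export a release bundle as published artifacts
#'
#' Writes each synthetic replicate as a CSV (provenance columns stripped) and
#' a `manifest.json` with the party id, K, N, seed, and the privacy ledger —
#' the complete "published" output of one party.
#'
#' @param bundle A `release_bundle`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_release_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "release_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_len(bundle$k)) {
    write_cohort_csv(bundle$replicates[[k]],
                     file.path(dir, sprintf("replicate_%03d.csv", k)))
  }
  pp <- bundle$privacy
  jsonlite::write_json(
    list(party = bundle$party, k = bundle$k, n = bundle$n, seed = bundle$seed,
         privacy = list(epsilon = pp$epsilon, delta = pp$delta,
                        noise_multiplier = pp$noise_multiplier,
                        subsampling_ratio = pp$subsampling_ratio,
                        iterations = pp$iterations,
                        realized_epsilon = pp$realized_epsilon)),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read an experiment configuration from a YAML file
#'
#' Accepts a nested key/value file mirroring the fields of
#' [experiment_config()] and [cohort_config()] (under a `cohort:` key);
#' omitted fields keep their defaults. Ground-truth generative parameters may
#' be given under `cohort: true_params_file:` as a path to a
#' [write_gen_params()] JSON.
#'
#' @param path YAML file path.
#' @param overrides Named list of experiment-level overrides (e.g. from
#'   command-line flags); applied after the file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$true_params_file)) {
    cohort_args$true_params <- read_gen_params(cohort_args$true_params_file)
    cohort_args$true_params_file <- NULL
  }
  if (!is.null(cohort_args$level_counts)) {
    cohort_args$level_counts <- as.integer(cohort_args$level_counts)
  }
  cohort <- do.call(cohort_config, cohort_args)
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(experiment_config, args)
}
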