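#' Release K synthetic replicates from a fitted posterior
#'
#' The K-repetition release protocol: for each replicate `k`, draw one
#' parameter vector from the variational posterior and sample a synthetic
#' dataset of size `n` from it. Sampling parameters anew for every replicate
#' propagates posterior uncertainty into the released data, which is what
#' lets recipients quantify it via Rubin's rules; by DP post-processing
#' immunity the K replicates cost no additional privacy budget. The bundle is
#' a pure function of `(post, k, n, seed)`.
#'
#' @param post A `dpvi_posterior` from [fit_dpvi()].
#' @param k Number of replicates (the conventional choice is 100).
#' @param n Records per replicate; by convention the size of the releasing
#'   party's local training set (`post$n_train`, the default).
#' @param party Identifier of the releasing party (stamped on records).
#' @param seed Integer seed.
#' @return An object of class `release_bundle`: fields `party`, `k`, `n`,
#'   `replicates` (list of tibbles with provenance columns `.party`,
#'   `.replicate`), `seed`, `privacy` (the releasing fit's privacy ledger).
#' @export
release_synthetic_sets <- function(post, k = 100, n = post$n_train,
                                   party = 1L, seed = 1) {
  stopifnot(inherits(post, "dpvi_posterior"), k >= 1, n >= 1)
  if (!all(is.finite(post$loc)) || !all(is.finite(post$log_scale))) {
    stop("posterior has non-finite location or scale")
  }
  replicates <- lapply(seq_len(k), function(kk) {
    params <- posterior_draw(post, derive_seed(seed, "draw", kk))
    ds <- sample_synthetic(params, n, derive_seed(seed, "sample", kk))
    ds$.party <- as.integer(party)
    ds$.replicate <- as.integer(kk)
    ds
  })
  structure(
    list(party = as.integer(party), k = as.integer(k), n = as.integer(n),
         replicates = replicates, seed = seed, privacy = post$privacy),
    class = "release_bundle"
  )
}

#' @export
print.release_bundle <- function(x, ...) {
  cat("<release_bundle> party", x$party, ":", x$k, "replicates of", x$n,
      "records\n")
  invisible(x)
}

#' Combine local data with received synthetic replicates
#'
#' Builds the K combined training sets of the collaborative protocol: the
#' k-th combined set is the party's own local data plus the k-th replicate of
#' every *other* party's bundle (a party never re-ingests its own synthetic
#' data; its information enters through the local records). Bundles are bound
#' in ascending party order so the result depends only on the set of sharing
#' parties, not on the order received.
#'
#' @param local_train The party's local training tibble.
#' @param bundles List of `release_bundle`s received from other parties.
#' @param k Number of combined sets to build; every bundle must hold at least
#'   `k` replicates.
#' @param exclude_party Party id whose bundle (if present among `bundles`) is
#'   dropped — the recipient's own.
#' @return A list of `k` tibbles; each contains the local records (stamped
#'   `.party = 0`, `.replicate = NA`) plus one replicate per other party.
#' @export
assemble_combined_sets <- function(local_train, bundles, k,
                                   exclude_party = NULL) {
  stopifnot(k >= 1)
  if (!is.null(exclude_party)) {
    bundles <- Filter(function(b) b$party != exclude_party, bundles)
  }
  for (b in bundles) {
    if (b$k < k) {
      stop("party ", b$party, " shared only ", b$k, " replicates; need ", k)
    }
  }
  ord <- order(vapply(bundles, function(b) b$party, integer(1)))
  bundles <- bundles[ord]
  local_tag <- local_train
  local_tag$.party <- 0L
  local_tag$.replicate <- NA_integer_
  lapply(seq_len(k), function(kk) {
    dplyr::bind_rows(c(list(local_tag),
                       lapply(bundles, function(b) b$replicates[[kk]])))
  })
}
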