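#' Derive a named child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its randomness from a seed
#' derived deterministically from one master seed and a sequence of labels
#' (stage name, repeat index, center id, ...). This gives named, effectively
#' independent streams: re-running any stage with the same master seed and
#' labels reproduces its output bitwise, and changing one stage's draws never
#' shifts another stage's stream.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param ... Labels (character or integer-valued scalars) naming the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "dpvi", 3, "center", 2)
#' @export
derive_seed <- function(seed, ...) {
  labels <- vapply(list(...), function(x) paste0(as.character(x), collapse = ","),
                   character(1))
  key <- paste(c(format(seed, scientific = FALSE), labels), collapse = "\r")
  # 31-ary polynomial rolling hash mod (2^31 - 1); exact in double precision
  # since intermediate values stay below 2^53.
  m <- 2147483647
  h <- 17
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1L) + 1)
}

# Run code with a derived seed without disturbing the caller's RNG state.
with_stream <- function(seed, ..., code) {
  withr::with_seed(derive_seed(seed, ...), code)
}
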