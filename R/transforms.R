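# Stick-breaking bijection between the (n-1)-dimensional unconstrained space
# and the interior of the n-simplex, with the log(n - k) offset so that z = 0
# maps to the uniform simplex. Used to put a mean-field Gaussian posterior on
# unconstrained coordinates of the mixture weights and the per-component
# categorical parameters.

# z (length n-1) -> list(p = simplex of length n, v = break fractions).
sb_forward <- function(z) {
  n <- length(z) + 1L
  if (n == 1L) return(list(p = 1, v = numeric(0)))
  k <- seq_len(n - 1L)
  v <- stats::plogis(z - log(n - k))
  cp <- cumprod(1 - v)
  p <- c(v * c(1, cp[-(n - 1L)]), cp[n - 1L])
  list(p = p, v = v)
}

# simplex (length n) -> unconstrained z (length n-1). Inverse of sb_forward.
sb_inverse <- function(p) {
  n <- length(p)
  if (n == 1L) return(numeric(0))
  k <- seq_len(n - 1L)
  head_cum <- c(0, cumsum(p))[k]
  v <- p[k] / (1 - head_cum)
  v <- pmin(pmax(v, 1e-15), 1 - 1e-15)
  stats::qlogis(v) + log(n - k)
}

# log |d p_{1..n-1} / d z| of the stick-breaking map, given break fractions v.
sb_log_det_jac <- function(v) {
  n <- length(v) + 1L
  if (n == 1L) return(0)
  k <- seq_len(n - 1L)
  sum(log(v) + (n - k) * log1p(-v))
}

# Gradient of sb_log_det_jac with respect to z.
sb_log_det_jac_grad <- function(v) {
  n <- length(v) + 1L
  if (n == 1L) return(numeric(0))
  k <- seq_len(n - 1L)
  (1 - v) - (n - k) * v
}

# Chain rule through the stick-breaking map: given the gradient `gp` of a
# scalar function with respect to the simplex p (length n), return the
# gradient with respect to z (length n-1).
#   d/dz_k = (1 - v_k) p_k gp_k - v_k * sum_{l > k} p_l gp_l
sb_chain_grad <- function(gp, p, v) {
  n <- length(p)
  if (n == 1L) return(numeric(0))
  t_ <- p * gp
  suffix <- sum(t_) - cumsum(t_)[seq_len(n - 1L)]
  (1 - v) * t_[seq_len(n - 1L)] - v * suffix
}
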