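# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# All set partitions of n items as integer label vectors (Bell(6) = 203).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    K <- max(p)
    for (k in seq_len(K + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

# Brute-force adjusted Rand index by explicit pair counting
# (Hubert-Arabie: chance-corrected pair agreement).
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Direct scalar evaluation of the known-concentration allocation posterior
# (CRP prior times predictive, normalised) for a partial allocation state.
known_beta_posterior <- function(x, X_prev, z_prev, beta, prior) {
  K <- if (length(z_prev)) max(z_prev) else 0L
  i <- length(z_prev) + 1L
  w <- numeric(K + 1L)
  lik <- numeric(K + 1L)
  for (k in seq_len(K)) {
    w[k] <- sum(z_prev == k) / (beta + i - 1)
    post <- prior
    members <- X_prev[z_prev == k, , drop = FALSE]
    lik[k] <- sum(vapply(seq_along(x), function(d) {
      ng_log_predictive(ng_update(prior, members[, d]), x[d])
    }, numeric(1)))
  }
  w[K + 1L] <- beta / (beta + i - 1)
  lik[K + 1L] <- sum(vapply(seq_along(x), function(d)
    ng_log_predictive(prior, x[d]), numeric(1)))
  u <- w * exp(lik - max(lik))
  u / sum(u)
}
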