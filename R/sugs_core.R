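#' Empty cluster state
#'
#' A cluster state holds, mid-pass, the allocations so far, the occupied
#' cluster sizes and the per-cluster, per-dimension Normal-Gamma posteriors.
#' Used by [allocation_posterior()] and the pure-R reference pass; the fast
#' path keeps the equivalent state in C++.
#'
#' @param D Number of variables.
#' @param prior An [ng_params()] prior shared by all (cluster, dimension)
#'   pairs.
#' @return An object of class `"cluster_state"`.
#' @export
cluster_state <- function(D, prior = ng_params()) {
  stopifnot(D >= 1, inherits(prior, "ng_params"))
  structure(list(allocations = integer(0), counts = integer(0),
                 posteriors = list(), D = as.integer(D), prior = prior),
            class = "cluster_state")
}

# Absorb observation x (length D) into cluster k (possibly new) of a state.
.state_add <- function(state, x, k) {
  K <- length(state$counts)
  if (k == K + 1L) {
    p <- state$prior
    state$posteriors[[k]] <- list(m = rep(p$m, state$D), c = rep(p$c, state$D),
                                  a = rep(p$a, state$D), b = rep(p$b, state$D))
    state$counts[k] <- 0L
  } else if (k < 1L || k > K + 1L) stop("invalid cluster label")
  po <- state$posteriors[[k]]
  cn <- po$c + 1
  d <- x - po$m
  po$b <- po$b + po$c * d^2 / (2 * cn)
  po$m <- (po$c * po$m + x) / cn
  po$c <- cn
  po$a <- po$a + 0.5
  state$posteriors[[k]] <- po
  state$counts[k] <- state$counts[k] + 1L
  state$allocations <- c(state$allocations, as.integer(k))
  state
}

# Student-t log predictive, vectorised over dimensions (m, c, a, b vectors).
.t_logpred <- function(m, cc, a, b, x) {
  z <- x - m
  lgamma(a + 0.5) - lgamma(a) - 0.5 * log(2 * pi * b * (cc + 1) / cc) -
    (a + 0.5) * log1p(z^2 * cc / (2 * b * (cc + 1)))
}

#' Posterior allocation distribution for one observation
#'
#' Combines the grid-marginalised CRP prior with the per-cluster Student-t
#' predictive likelihood to give the posterior probability of allocating a
#' new observation to each occupied cluster or to a new one. When a variable
#' mask is supplied, only mask-on dimensions enter the likelihood (mask-off
#' dimensions contribute a factor common to all clusters, which cancels).
#'
#' @param x Observation vector of length `D`.
#' @param state A [cluster_state()] holding the previous allocations.
#' @param grid A [beta_grid()]; its `posterior_weights` are the current
#'   sequential weights.
#' @param mask Optional 0/1 vector of length `D`; `NULL` means all on.
#' @return A list of class `"allocation_distribution"` with `probs`
#'   (length `K`, last entry the new cluster), `per_grid_prior`
#'   (`K x L` CRP prior matrix) and `predictive` (log predictive per
#'   candidate cluster).
#' @export
allocation_posterior <- function(x, state, grid, mask = NULL) {
  stopifnot(inherits(state, "cluster_state"), inherits(grid, "beta_grid"))
  if (length(x) != state$D) stop("dimension mismatch between x and state")
  on <- if (is.null(mask)) seq_len(state$D) else which(mask == 1)
  Ke <- length(state$counts)
  i <- length(state$allocations) + 1L
  beta <- grid$values
  phi <- grid$posterior_weights
  pgp <- rbind(outer(state$counts, beta + i - 1, "/"),
               beta / (beta + i - 1))
  pred <- numeric(Ke + 1L)
  for (k in seq_len(Ke)) {
    po <- state$posteriors[[k]]
    pred[k] <- sum(.t_logpred(po$m[on], po$c[on], po$a[on], po$b[on], x[on]))
  }
  p <- state$prior
  pred[Ke + 1L] <- sum(.t_logpred(rep(p$m, length(on)), p$c, p$a, p$b, x[on]))
  lw <- log(drop(pgp %*% phi)) + pred
  probs <- exp(lw - .logsumexp(lw))
  probs <- probs / sum(probs)
  structure(list(probs = probs, per_grid_prior = pgp, predictive = pred),
            class = "allocation_distribution")
}

# Pure-R reference implementation of one sequential greedy pass; mirrors the
# C++ engine and is cross-checked against it in the test suite.
.sugs_pass_r <- function(X, ordering, prior, grid, mask = NULL) {
  n <- length(ordering)
  state <- cluster_state(ncol(X), prior)
  grid$posterior_weights <- grid$prior_weights
  z <- integer(nrow(X))
  for (t in seq_len(n)) {
    x <- X[ordering[t], ]
    ad <- allocation_posterior(x, state, grid, mask)
    k <- which.max(ad$probs)  # ties -> lowest label
    grid <- update_beta_posterior(grid, ad$per_grid_prior[k, ])
    state <- .state_add(state, x, k)
    z[ordering[t]] <- k
  }
  list(z = z, phi = grid$posterior_weights, counts = state$counts)
}

.validate_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  if (nrow(X) < 1L || ncol(X) < 1L) stop("X must have at least one row and column")
  if (any(!is.finite(X))) stop("X must not contain missing or non-finite values")
  X
}

.validate_mask <- function(mask, D) {
  if (is.null(mask)) return(NULL)
  mask <- as.integer(mask)
  if (length(mask) != D || any(!mask %in% c(0L, 1L)))
    stop("mask must be a 0/1 vector of length ncol(X)")
  if (sum(mask) == 0L) stop("mask must have at least one variable switched on")
  mask
}

#' Single-ordering greedy fit
#'
#' Runs one deterministic sequential pass: observations are visited in
#' `ordering`; each is allocated to the cluster maximising the posterior
#' allocation probability (ties to the lowest label), the concentration-grid
#' posterior is updated, and the chosen cluster's Normal-Gamma posterior
#' absorbs the observation. Past allocations are never revised. The finished
#' partition is scored by its log marginal likelihood and log pseudo-marginal
#' likelihood.
#'
#' @param X Numeric data matrix (`n x D`), no missing values.
#' @param ordering Permutation of `1:nrow(X)` (default: natural order).
#' @param prior [ng_params()] prior.
#' @param grid [beta_grid()] concentration grid.
#' @param mask Optional 0/1 relevance mask (`NULL` = all variables on).
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @param scores Compute model scores (set `FALSE` to skip, e.g. mid-iteration).
#' @return A `"sugs_model"` record: `allocations` (in the original row order,
#'   labels contiguous from 1 in order of creation), `mask`, `log_ml`,
#'   `log_pml`, `beta_posterior`, `counts`, `n_clusters`, `ordering`.
#' @export
sugs_fit <- function(X, ordering = seq_len(nrow(X)), prior = ng_params(),
                     grid = beta_grid(), mask = NULL,
                     engine = c("cpp", "r"), scores = TRUE) {
  X <- .validate_matrix(X)
  engine <- match.arg(engine)
  n <- nrow(X)
  if (length(ordering) != n || !setequal(ordering, seq_len(n)))
    stop("'ordering' must be a permutation of 1:nrow(X)")
  mask <- .validate_mask(mask, ncol(X))
  on <- if (is.null(mask)) seq_len(ncol(X)) else which(mask == 1L)
  res <- if (engine == "cpp") {
    sugs_pass_cpp(X, as.integer(ordering), as.integer(on),
                  prior$m, prior$c, prior$a, prior$b,
                  grid$values, grid$prior_weights)
  } else {
    .sugs_pass_r(X, as.integer(ordering), prior, grid, mask)
  }
  gfit <- grid
  gfit$posterior_weights <- res$phi
  out <- structure(list(allocations = res$z,
                        mask = if (is.null(mask)) rep(1L, ncol(X)) else mask,
                        log_ml = NA_real_, log_pml = NA_real_,
                        beta_posterior = res$phi, counts = res$counts,
                        n_clusters = max(res$z), ordering = as.integer(ordering)),
                   class = "sugs_model")
  if (scores) {
    out$log_ml <- log_marginal_likelihood(X, res$z, prior, mask)
    out$log_pml <- log_pseudo_marginal(X, res$z, prior, gfit, mask)
  }
  out
}

#' @export
print.sugs_model <- function(x, ...) {
  cat(sprintf("Greedy DP fit: %d observations, %d clusters (sizes: %s)\n",
              length(x$allocations), x$n_clusters,
              paste(x$counts, collapse = ", ")))
  cat(sprintf("  variables on: %d / %d\n", sum(x$mask), length(x$mask)))
  cat(sprintf("  log ML: %.3f   log PML: %.3f\n", x$log_ml, x$log_pml))
  invisible(x)
}

#' Log marginal likelihood of a partition
#'
#' Integrated likelihood of the data given the partition under the conjugate
#' model: the product over clusters and mask-on dimensions of Normal-Gamma
#' evidences, times the single-component (global) evidence of each mask-off
#' column. Invariant to cluster relabelling.
#'
#' @inheritParams sugs_fit
#' @param Z Integer partition covering all rows of `X`.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, Z, prior = ng_params(), mask = NULL) {
  X <- .validate_matrix(X)
  stopifnot(length(Z) == nrow(X), all(Z >= 1))
  mask <- .validate_mask(mask, ncol(X))
  clustered <- colSums(.cluster_evidence(X, Z, prior))
  if (is.null(mask)) return(sum(clustered))
  off <- which(mask == 0L)
  total <- sum(clustered[mask == 1L])
  if (length(off)) total <- total + sum(.global_evidence(X, prior)[off])
  total
}

# K x D matrix of per-cluster, per-column Normal-Gamma evidences.
.cluster_evidence <- function(X, Z, prior, X2 = NULL) {
  cs <- .cluster_stats(X, Z, X2)
  .ng_evidence(cs$nk, cs$xbar, cs$ss, prior)
}

# Length-D vector of single-component evidences (does not depend on Z).
.global_evidence <- function(X, prior, X2 = NULL) {
  n <- nrow(X)
  xbar <- colMeans(X)
  S2 <- if (is.null(X2)) colSums(X * X) else colSums(X2)
  ss <- pmax(S2 - n * xbar^2, 0)
  .ng_evidence(n, xbar, ss, prior)
}

# n x (K+1) log predictive matrix of every observation under every cluster's
# full-data posterior (last column: prior predictive), mask-on columns only.
.predictive_matrix <- function(X, Z, prior, on) {
  Xon <- X[, on, drop = FALSE]
  n <- nrow(X); Don <- length(on)
  cs <- .cluster_stats(Xon, Z)
  K <- length(cs$nk)
  m0 <- prior$m; c0 <- prior$c; a0 <- prior$a; b0 <- prior$b
  out <- matrix(0, n, K + 1L)
  for (k in seq_len(K)) {
    nk <- cs$nk[k]
    cn <- c0 + nk; an <- a0 + nk / 2
    mk <- (c0 * m0 + nk * cs$xbar[k, ]) / cn
    bk <- b0 + cs$ss[k, ] / 2 + c0 * nk * (cs$xbar[k, ] - m0)^2 / (2 * cn)
    Zc <- sweep(Xon, 2, mk)
    q <- sweep(Zc^2, 2, cn / (2 * bk * (cn + 1)), "*")
    out[, k] <- Don * (lgamma(an + 0.5) - lgamma(an) -
                         0.5 * log(2 * pi * (cn + 1) / cn)) -
      0.5 * sum(log(bk)) - (an + 0.5) * rowSums(log1p(q))
  }
  q0 <- (Xon - m0)^2 * c0 / (2 * b0 * (c0 + 1))
  out[, K + 1L] <- Don * (lgamma(a0 + 0.5) - lgamma(a0) -
                            0.5 * log(2 * pi * b0 * (c0 + 1) / c0)) -
    (a0 + 0.5) * rowSums(log1p(q0))
  out
}

# Row-wise log-sum-exp of a matrix.
.row_logsumexp <- function(M) {
  m <- do.call(pmax, as.data.frame(M))
  m + log(rowSums(exp(M - m)))
}

#' Log pseudo-marginal likelihood of a partition
#'
#' Product over observations of leave-one-out predictive densities, mixing
#' over clusters with the grid-marginalised CRP prior weights. By default the
#' full-data posterior approximates the leave-one-out posterior (accurate for
#' large samples and much cheaper); `exact = TRUE` computes the true
#' leave-one-out quantity by downdating sufficient statistics.
#'
#' @inheritParams log_marginal_likelihood
#' @param grid A [beta_grid()] whose `posterior_weights` are the final
#'   sequential weights of the fit being scored.
#' @param exact Use the exact leave-one-out computation (default `FALSE`).
#' @return Scalar log pseudo-marginal likelihood.
#' @export
log_pseudo_marginal <- function(X, Z, prior = ng_params(), grid = beta_grid(),
                                mask = NULL, exact = FALSE) {
  X <- .validate_matrix(X)
  stopifnot(length(Z) == nrow(X))
  mask <- .validate_mask(mask, ncol(X))
  on <- if (is.null(mask)) seq_len(ncol(X)) else which(mask == 1L)
  off <- setdiff(seq_len(ncol(X)), on)
  n <- nrow(X)
  counts <- tabulate(Z)
  K <- length(counts)
  beta <- grid$values; phi <- grid$posterior_weights
  lp <- .predictive_matrix(X, Z, prior, on)
  if (!exact) {
    den <- beta + n
    logw <- log(c(counts * sum(phi / den), sum(phi * beta / den)))
    total <- sum(.row_logsumexp(sweep(lp, 2, logw, "+")))
    if (length(off)) total <- total + .global_predictive_sum(X, prior, off, exact = FALSE)
    return(total)
  }
  # exact leave-one-out: correct own-cluster predictive and CRP weights
  den <- beta + n - 1
  s_exist <- sum(phi / den); s_new <- sum(phi * beta / den)
  Xon <- X[, on, drop = FALSE]
  cs <- .cluster_stats(Xon, Z)
  m0 <- prior$m; c0 <- prior$c; a0 <- prior$a; b0 <- prior$b
  total <- 0
  for (i in seq_len(n)) {
    zi <- Z[i]
    lw <- numeric(K + 1L)
    cnt <- counts; cnt[zi] <- cnt[zi] - 1L
    lw[seq_len(K)] <- log(cnt * s_exist)  # -Inf for emptied singleton
    lw[K + 1L] <- log(s_new)
    row <- lp[i, ]
    nk <- counts[zi] - 1L
    if (nk == 0L) {
      row[zi] <- lp[i, K + 1L]  # leave-one-out posterior is the prior
    } else {
      xb <- (counts[zi] * cs$xbar[zi, ] - Xon[i, ]) / nk
      ssv <- pmax(cs$ss[zi, ] - (Xon[i, ] - cs$xbar[zi, ])^2 * counts[zi] / nk, 0)
      cn <- c0 + nk; an <- a0 + nk / 2
      mk <- (c0 * m0 + nk * xb) / cn
      bk <- b0 + ssv / 2 + c0 * nk * (xb - m0)^2 / (2 * cn)
      row[zi] <- sum(.t_logpred(mk, cn, an, bk, Xon[i, ]))
    }
    total <- total + .logsumexp(lw + row)
  }
  if (length(off)) total <- total + .global_predictive_sum(X, prior, off, exact = TRUE)
  total
}

# Sum over observations and mask-off columns of the log predictive under the
# single global component (full-data or leave-one-out posterior).
.global_predictive_sum <- function(X, prior, off, exact = FALSE) {
  Xo <- X[, off, drop = FALSE]
  n <- nrow(Xo)
  m0 <- prior$m; c0 <- prior$c; a0 <- prior$a; b0 <- prior$b
  if (!exact) {
    xbar <- colMeans(Xo)
    ss <- pmax(colSums(Xo^2) - n * xbar^2, 0)
    cn <- c0 + n; an <- a0 + n / 2
    mk <- (c0 * m0 + n * xbar) / cn
    bk <- b0 + ss / 2 + c0 * n * (xbar - m0)^2 / (2 * cn)
    q <- sweep(sweep(Xo, 2, mk)^2, 2, cn / (2 * bk * (cn + 1)), "*")
    return(n * length(off) * (lgamma(an + 0.5) - lgamma(an) -
                                0.5 * log(2 * pi * (cn + 1) / cn)) -
             0.5 * n * sum(log(bk)) - (an + 0.5) * sum(log1p(q)))
  }
  total <- 0
  xbar <- colMeans(Xo)
  ss <- pmax(colSums(Xo^2) - n * xbar^2, 0)
  for (i in seq_len(n)) {
    np <- n - 1L
    if (np == 0L) { total <- total + sum(.t_logpred(rep(m0, length(off)), c0, a0, b0, Xo[i, ])); next }
    xb <- (n * xbar - Xo[i, ]) / np
    ssv <- pmax(ss - (Xo[i, ] - xbar)^2 * n / np, 0)
    cn <- c0 + np; an <- a0 + np / 2
    mk <- (c0 * m0 + np * xb) / cn
    bk <- b0 + ssv / 2 + c0 * np * (xb - m0)^2 / (2 * cn)
    total <- total + sum(.t_logpred(mk, cn, an, bk, Xo[i, ]))
  }
  total
}
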