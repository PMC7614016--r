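test_that("CRP weights follow the conditional prior", {
  expect_equal(crp_weights(c(2, 1), i = 4, beta = 1), c(0.5, 0.25, 0.25))
  # first observation: all mass on the new cluster
  expect_equal(crp_weights(integer(0), i = 1, beta = 2), 1)
  # large-concentration limit: new cluster dominates
  w <- crp_weights(c(2, 1), i = 4, beta = 1e9)
  expect_gt(w[3], 1 - 1e-8)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(crp_weights(c(2, 1), i = 4, beta = 0), "positive")
  expect_error(crp_weights(c(2, 1), i = 3, beta = 1), "previous")
})

test_that("concentration-grid posterior updates sequentially", {
  g <- beta_grid(values = c(1, 10), prior_weights = c(0.5, 0.5))
  # uniform likelihood across the grid leaves the posterior unchanged
  g1 <- update_beta_posterior(g, c(0.3, 0.3))
  expect_equal(g1$posterior_weights, c(0.5, 0.5))
  # i = 2, allocation to the existing singleton: pi_l = 1/(beta_l + 1)
  g2 <- update_beta_posterior(g, 1 / (c(1, 10) + 1))
  expect_equal(g2$posterior_weights[1],
               (0.5 * 0.5) / (0.5 * 0.5 + 0.5 / 11), tolerance = 1e-12)
  expect_error(update_beta_posterior(g, c(0, 0)), "degenerate")
  # repeated allocations to existing clusters favour smaller beta
  g3 <- g
  for (i in 2:20) g3 <- update_beta_posterior(g3, 1 / (c(1, 10) + i - 1))
  expect_gt(g3$posterior_weights[1], 0.9)
  expect_equal(sum(g3$posterior_weights), 1, tolerance = 1e-12)
})

test_that("allocation posterior reduces to the known-concentration form", {
  prior <- ng_params()
  set.seed(3)
  X_prev <- matrix(rnorm(6), 3, 2)
  z_prev <- c(1L, 1L, 2L)
  x <- rnorm(2)
  state <- cluster_state(2, prior)
  for (i in 1:3) state <- sugsclust:::.state_add(state, X_prev[i, ], z_prev[i])
  # singleton grid: must equal the direct scalar evaluation
  g1 <- beta_grid(values = 2.5, prior_weights = 1)
  ad <- allocation_posterior(x, state, g1)
  expect_equal(ad$probs, known_beta_posterior(x, X_prev, z_prev, 2.5, prior),
               tolerance = 1e-10)
  expect_equal(sum(ad$probs), 1, tolerance = 1e-12)
  # two-point grid: exhaustive scalar mixture over grid values
  g2 <- beta_grid(values = c(0.5, 5), prior_weights = c(0.4, 0.6))
  ad2 <- allocation_posterior(x, state, g2)
  manual <- numeric(3)
  for (k in 1:3) {
    for (l in 1:2) {
      pik <- crp_weights(c(2, 1), i = 4, beta = g2$values[l])[k]
      lik <- exp(ad2$predictive[k])
      manual[k] <- manual[k] + g2$prior_weights[l] * pik * lik
    }
  }
  expect_equal(ad2$probs, manual / sum(manual), tolerance = 1e-10)
  # symmetric duplicate clusters get equal probability
  Xs <- rbind(c(1, 1), c(-1, -1), c(1, 1), c(-1, -1))
  st <- cluster_state(2, prior)
  for (i in 1:4) st <- sugsclust:::.state_add(st, Xs[i, ], c(1L, 2L, 1L, 2L)[i])
  ads <- allocation_posterior(c(0, 0), st, beta_grid())
  expect_equal(ads$probs[1], ads$probs[2], tolerance = 1e-12)
})

test_that("greedy pass is deterministic and the engines agree", {
  set.seed(11)
  X <- matrix(rnorm(30 * 4), 30, 4)
  o <- sample(30)
  a <- sugs_fit(X, o, engine = "cpp")
  b <- sugs_fit(X, o, engine = "r")
  expect_identical(a$allocations, b$allocations)
  expect_equal(a$beta_posterior, b$beta_posterior, tolerance = 1e-9)
  expect_equal(a$log_ml, b$log_ml, tolerance = 1e-9)
  expect_identical(a$allocations, sugs_fit(X, o)$allocations)  # bit-for-bit
  # labels contiguous, first-visited observation gets label 1
  expect_identical(sort(unique(a$allocations)), seq_len(a$n_clusters))
  expect_identical(a$allocations[o[1]], 1L)
  expect_equal(sum(a$beta_posterior), 1, tolerance = 1e-12)
  # masked engines agree too
  m <- c(1L, 0L, 1L, 0L)
  am <- sugs_fit(X, o, mask = m, engine = "cpp")
  bm <- sugs_fit(X, o, mask = m, engine = "r")
  expect_identical(am$allocations, bm$allocations)
  expect_error(sugs_fit(X[0, , drop = FALSE]), "at least one row")
})

test_that("well-separated groups are recovered under any ordering", {
  set.seed(5)
  truth <- rep(1:2, each = 10)
  X <- matrix(rnorm(20 * 10), 20, 10) + c(-3, 3)[truth]
  for (r in 1:5) {
    f <- sugs_fit(X, sample(20))
    expect_equal(f$n_clusters, 2L)
    expect_equal(adjusted_rand_index(f$allocations, truth), 1)
  }
  # single observation: one cluster
  f1 <- sugs_fit(X[1, , drop = FALSE])
  expect_identical(f1$allocations, 1L)
})

test_that("cluster posteriors equal batch updates of final members", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  o <- sample(20)
  res <- sugsclust:::.sugs_pass_r(X, o, ng_params(), beta_grid())
  state <- cluster_state(2, ng_params())
  for (i in o) state <- sugsclust:::.state_add(state, X[i, ], res$z[i])
  for (k in seq_along(res$counts)) {
    for (d in 1:2) {
      batch <- ng_update(ng_params(), X[res$z == k, d])
      po <- state$posteriors[[k]]
      expect_equal(c(po$m[d], po$c[d], po$a[d], po$b[d]),
                   c(batch$m, batch$c, batch$a, batch$b), tolerance = 1e-9)
    }
  }
})

test_that("marginal likelihood of a partition matches scalar computation", {
  prior <- ng_params()
  set.seed(13)
  X <- matrix(rnorm(8), 4, 2)
  Z <- c(1L, 1L, 2L, 2L)
  manual <- 0
  for (k in 1:2) for (d in 1:2)
    manual <- manual + ng_log_marginal(prior, X[Z == k, d])
  expect_equal(log_marginal_likelihood(X, Z, prior), manual, tolerance = 1e-10)
  # relabelling invariance
  expect_equal(log_marginal_likelihood(X, c(2L, 2L, 1L, 1L), prior),
               log_marginal_likelihood(X, Z, prior), tolerance = 1e-12)
  # K = 1 reduction: sum of per-column evidences
  expect_equal(log_marginal_likelihood(X, rep(1L, 4), prior),
               ng_log_marginal(prior, X[, 1]) + ng_log_marginal(prior, X[, 2]),
               tolerance = 1e-10)
  # masked factorisation: off columns contribute the global evidence
  mask <- c(1L, 0L)
  expect_equal(log_marginal_likelihood(X, Z, prior, mask),
               ng_log_marginal(prior, X[Z == 1, 1]) +
                 ng_log_marginal(prior, X[Z == 2, 1]) +
                 ng_log_marginal(prior, X[, 2]),
               tolerance = 1e-10)
})

test_that("pseudo-marginal likelihood: degenerate case, LOO agreement, ranking", {
  prior <- ng_params()
  g <- beta_grid()
  # n = 1: exact PML is the prior predictive of the single point
  X1 <- matrix(c(0.4, -1.2), 1, 2)
  expect_equal(log_pseudo_marginal(X1, 1L, prior, g, exact = TRUE),
               ng_log_predictive(prior, 0.4) + ng_log_predictive(prior, -1.2),
               tolerance = 1e-10)
  # exact leave-one-out equals a brute-force refit oracle on a small dataset
  set.seed(20)
  n <- 12
  Xb <- matrix(rnorm(n * 3), n, 3)
  Zb <- sample(2, n, replace = TRUE)
  gb <- beta_grid(values = c(0.5, 5), prior_weights = c(0.3, 0.7))
  gb$posterior_weights <- c(0.6, 0.4)
  brute_pml <- function(mask) {
    on <- which(mask == 1); off <- which(mask == 0)
    tot <- 0
    for (i in seq_len(n)) {
      cnt <- tabulate(Zb[-i], nbins = max(Zb))
      K <- max(Zb)
      lw <- lik <- numeric(K + 1)
      for (k in seq_len(K)) {
        lw[k] <- log(sum(gb$posterior_weights * cnt[k] / (gb$values + n - 1)))
        lik[k] <- sum(vapply(on, function(d)
          ng_log_predictive(ng_update(prior, Xb[setdiff(which(Zb == k), i), d]),
                            Xb[i, d]), numeric(1)))
      }
      lw[K + 1] <- log(sum(gb$posterior_weights * gb$values / (gb$values + n - 1)))
      lik[K + 1] <- sum(vapply(on, function(d)
        ng_log_predictive(prior, Xb[i, d]), numeric(1)))
      m <- max(lw + lik)
      tot <- tot + m + log(sum(exp(lw + lik - m)))
      for (d in off)
        tot <- tot + ng_log_predictive(ng_update(prior, Xb[-i, d]), Xb[i, d])
    }
    tot
  }
  expect_equal(log_pseudo_marginal(Xb, Zb, prior, gb, exact = TRUE),
               brute_pml(c(1L, 1L, 1L)), tolerance = 1e-9)
  expect_equal(log_pseudo_marginal(Xb, Zb, prior, gb, c(1L, 1L, 0L),
                                   exact = TRUE),
               brute_pml(c(1L, 1L, 0L)), tolerance = 1e-9)
  # full-data approximation close to exact leave-one-out at n = 500 (O(1/n))
  sim <- simulate_mixture(n = 500, D = 4, n_relevant = 4, seed = 21)
  f <- sugs_fit(sim$X, sample(500))
  gfit <- g; gfit$posterior_weights <- f$beta_posterior
  ap <- log_pseudo_marginal(sim$X, f$allocations, prior, gfit)
  ex <- log_pseudo_marginal(sim$X, f$allocations, prior, gfit, exact = TRUE)
  expect_lt(abs(ap - ex) / abs(ex), 0.02)
  # masked variant is consistent between the two routes as well
  mask <- c(1L, 1L, 0L, 0L)
  apm <- log_pseudo_marginal(sim$X, f$allocations, prior, gfit, mask)
  exm <- log_pseudo_marginal(sim$X, f$allocations, prior, gfit, mask, exact = TRUE)
  expect_lt(abs(apm - exm) / abs(exm), 0.02)
  # the true partition beats a random partition on separated data
  sim2 <- simulate_mixture(n = 60, D = 3, n_relevant = 3,
                           means = c(-6, 6, 0), seed = 22)
  set.seed(22)
  rand_Z <- sample(3, 60, replace = TRUE)
  expect_gt(log_pseudo_marginal(sim2$X, sim2$labels, prior, g),
            log_pseudo_marginal(sim2$X, rand_Z, prior, g))
})
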