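test_that("variable relevance scores follow the clustered-vs-global evidence", {
  prior <- ng_params()
  # K = 1: clustered and global evidence coincide, scores tie at prior 0.5
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2)
  s <- variable_log_posterior(X, rep(1L, 10), d = 1, prior, prior_on = 0.5)
  expect_equal(s[["on"]], s[["off"]], tolerance = 1e-12)
  # separated column clearly relevant
  Xt <- cbind(c(-5, -5, 5, 5), rnorm(4))
  st <- variable_log_posterior(Xt, c(1L, 1L, 2L, 2L), d = 1, prior)
  expect_gt(st[["on"]], st[["off"]])
  # scalar oracle: direct evaluation via per-cluster evidences
  manual_on <- log(0.5) + ng_log_marginal(prior, Xt[1:2, 1]) +
    ng_log_marginal(prior, Xt[3:4, 1])
  manual_off <- log(0.5) + ng_log_marginal(prior, Xt[, 1])
  expect_equal(unname(st), c(manual_on, manual_off), tolerance = 1e-10)
  expect_error(variable_log_posterior(Xt, c(1L, 1L, 2L, 2L), d = 9, prior),
               "range")
  # pure-noise columns against an arbitrary balanced split: usually irrelevant
  set.seed(32)
  Z <- rep(1:2, each = 50)
  hits <- 0
  for (r in 1:20) {
    Xn <- matrix(rnorm(100), 100, 1)
    sn <- variable_log_posterior(Xn, Z, 1, prior)
    hits <- hits + (sn[["off"]] > sn[["on"]])
  }
  expect_gte(hits, 16)
})

test_that("greedy indicator update is vectorised, tie-broken on, idempotent", {
  prior <- ng_params()
  # identical noise columns, single cluster: exact ties resolve to on
  set.seed(33)
  col <- rnorm(12)
  X <- cbind(col, col, col)
  expect_identical(greedy_variable_update(X, rep(1L, 12), prior),
                   c(1L, 1L, 1L))
  # per-variable independence: permuting columns permutes the mask
  sim <- simulate_mixture(n = 60, D = 10, n_relevant = 4, seed = 34)
  m1 <- greedy_variable_update(sim$X, sim$labels, prior)
  perm <- sample(10)
  m2 <- greedy_variable_update(sim$X[, perm], sim$labels, prior)
  expect_identical(m2, m1[perm])
  # matches the per-variable scalar scores
  for (d in c(1L, 7L)) {
    s <- variable_log_posterior(sim$X, sim$labels, d, prior)
    expect_identical(m1[d], as.integer(s[["on"]] >= s[["off"]]))
  }
  # idempotence on a fixed partition
  expect_identical(greedy_variable_update(sim$X, sim$labels, prior), m1)
  # benchmark-style data with the true partition: perfect recovery
  big <- simulate_mixture(n = 100, D = 200, relevant_fraction = 0.5, seed = 35)
  mb <- greedy_variable_update(big$X, big$labels, prior)
  vrb <- variable_recovery(mb, big$mask)
  expect_equal(vrb[["relevant"]], 1)
  expect_gte(vrb[["irrelevant"]], 0.95)
})

test_that("alternating fit honours the mask contract", {
  prior <- ng_params()
  sim <- simulate_mixture(n = 40, D = 4, n_relevant = 4,
                          means = c(-6, 6, 0), seed = 36)
  o <- sample(40)
  # T = 1 with an all-on mask clusters exactly like the plain pass
  fv <- sugsvarsel_fit(sim$X, rep(1L, 4), o, prior, iterations = 1)
  fp <- sugs_fit(sim$X, o, prior)
  expect_identical(fv$allocations, fp$allocations)
  # deterministic given all inputs
  expect_identical(sugsvarsel_fit(sim$X, rep(1L, 4), o, prior)$mask,
                   sugsvarsel_fit(sim$X, rep(1L, 4), o, prior)$mask)
  # reported log-ML equals the masked factorisation recomputed monolithically
  expect_equal(fv$log_ml,
               log_marginal_likelihood(sim$X, fv$allocations, prior, fv$mask),
               tolerance = 1e-10)
  # degenerate all-off update: previous mask is kept
  set.seed(37)
  noise <- matrix(rnorm(200), 50, 4)
  fn <- sugsvarsel_fit(noise, rep(1L, 4), sample(50), prior,
                       prior_on = 0.01)
  expect_gte(sum(fn$mask), 1L)
  expect_error(sugsvarsel_fit(sim$X, rep(0L, 4), o, prior), "at least one")
})

test_that("sub-sampling initialisation and the ensemble driver are reproducible", {
  sim <- simulate_mixture(n = 50, D = 12, n_relevant = 6, seed = 38)
  set.seed(1)
  masks <- subsample_initialise(sim$X, subsample_fraction = 0.5,
                                n_subsamples = 3, init_orderings = 2)
  expect_length(masks, 3)
  expect_true(all(vapply(masks, length, integer(1)) == 12))
  expect_true(all(unlist(masks) %in% 0:1))
  set.seed(1)
  masks2 <- subsample_initialise(sim$X, subsample_fraction = 0.5,
                                 n_subsamples = 3, init_orderings = 2)
  expect_identical(masks, masks2)
  expect_error(subsample_initialise(sim$X, subsample_fraction = 0.05,
                                    n_subsamples = 1), "at least 2")
  # degenerate sub-sample: fraction 1, M = 1 is one full-variable run
  set.seed(2)
  m1 <- subsample_initialise(sim$X, subsample_fraction = 1, n_subsamples = 1,
                             init_orderings = 1)
  expect_length(m1, 1)
  # ensemble bookkeeping: Q x M records, each scored
  set.seed(3)
  recs <- run_ensemble(sim$X, masks, orderings = 2)
  expect_length(recs, 6)
  expect_true(all(is.finite(vapply(recs, function(r) r$score, numeric(1)))))
  set.seed(3)
  r1 <- run_ensemble(sim$X, masks[1], orderings = 1)
  expect_length(r1, 1)
})

test_that("full fit selects the maximum-score model and recovers structure", {
  sim <- simulate_mixture(n = 100, D = 40, n_relevant = 20, seed = 39)
  set.seed(39)
  fit <- sugs_varsel(sim$X, subsample_fraction = 0.25, n_subsamples = 5,
                     orderings = 10, init_orderings = 5)
  expect_s3_class(fit, "sugsvarsel")
  expect_equal(fit$scores[fit$best], max(fit$scores))
  expect_length(fit$records, 50)
  # a modest ensemble recovers most of the structure; the full benchmark
  # protocol (20 sub-samples x 30 orderings) reaches ARI 1 in the
  # acceptance suite
  expect_gte(adjusted_rand_index(fit$allocations, sim$labels), 0.6)
  vr <- variable_recovery(fit$mask, sim$mask)
  expect_gte(vr[["relevant"]], 0.9)
  expect_gte(vr[["irrelevant"]], 0.9)
  # scheduling independence: same RNG seed, different worker counts
  set.seed(40)
  f1 <- sugs_varsel(sim$X, subsample_fraction = 0.5, n_subsamples = 2,
                    orderings = 2, init_orderings = 2, workers = 1)
  set.seed(40)
  f2 <- sugs_varsel(sim$X, subsample_fraction = 0.5, n_subsamples = 2,
                    orderings = 2, init_orderings = 2, workers = 2)
  expect_identical(f1$allocations, f2$allocations)
  expect_identical(f1$mask, f2$mask)
  expect_equal(f1$bmac, f2$bmac)
  # predict on the training data reproduces the fitted hard labels closely
  pr <- predict(fit, type = "class")
  expect_gte(mean(pr == fit$allocations), 0.9)
})
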