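test_that("conjugate update matches closed form and is exchangeable", {
  p <- ng_params(m = 0, c = 1, a = 1, b = 1)
  # symmetric observation at the prior mean: no squared deviation added
  u <- ng_update(p, 0)
  expect_equal(unclass(u)[c("m", "c", "a", "b")],
               list(m = 0, c = 2, a = 1.5, b = 1))
  # empty batch is the identity
  expect_identical(ng_update(p, numeric(0)), p)
  # all 6 orderings of sequential updates equal the batch update
  xs <- c(1.0, -1.0, 2.0)
  batch <- ng_update(p, xs)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) {
    seq_post <- Reduce(ng_update, as.list(xs[pm]), accumulate = FALSE, init = p)
    expect_equal(unlist(unclass(seq_post)), unlist(unclass(batch)),
                 tolerance = 1e-12)
  }
  expect_error(ng_update(p, NaN), "finite")
  expect_error(ng_params(c = -1), "positive")
})

test_that("posterior predictive is the scaled Student-t and integrates to 1", {
  p <- ng_params(m = 0, c = 1, a = 1, b = 1)
  expect_equal(ng_log_predictive(p, 0), log(0.25), tolerance = 1e-12)
  # symmetry about the location
  expect_equal(ng_log_predictive(p, 0.7), ng_log_predictive(p, -0.7))
  # independent oracle: location-scale transform of stats::dt
  set.seed(42)
  for (r in 1:5) {
    q <- ng_params(m = rnorm(1), c = runif(1, 0.1, 3),
                   a = runif(1, 0.5, 4), b = runif(1, 0.5, 4))
    s <- sqrt(q$b * (q$c + 1) / (q$a * q$c))
    x <- rnorm(3, q$m, 2)
    expect_equal(ng_log_predictive(q, x),
                 dt((x - q$m) / s, df = 2 * q$a, log = TRUE) - log(s),
                 tolerance = 1e-12)
    # quadrature oracle: density normalises
    f <- function(v) exp(ng_log_predictive(q, v))
    expect_equal(integrate(f, -Inf, Inf, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("marginal likelihood obeys the chain rule and exchangeability", {
  p <- ng_params(m = 0, c = 1, a = 1, b = 1)
  expect_identical(ng_log_marginal(p, numeric(0)), 0)
  expect_equal(ng_log_marginal(p, 0), log(0.25), tolerance = 1e-12)
  set.seed(7)
  for (r in 1:10) {
    q <- ng_params(m = rnorm(1), c = runif(1, 0.1, 3),
                   a = runif(1, 0.5, 4), b = runif(1, 0.5, 4))
    xs <- rnorm(sample(2:8, 1), sd = 2)
    # chain rule: evidence = sum of sequential log predictives
    chain <- 0
    post <- q
    for (x in xs) {
      chain <- chain + ng_log_predictive(post, x)
      post <- ng_update(post, x)
    }
    expect_equal(ng_log_marginal(q, xs), chain, tolerance = 1e-10)
    # permutation invariance
    expect_equal(ng_log_marginal(q, sample(xs)), ng_log_marginal(q, xs),
                 tolerance = 1e-10)
    # chain-rule increment equals the predictive at the posterior
    y <- rnorm(1)
    expect_equal(ng_log_marginal(q, c(xs, y)) - ng_log_marginal(q, xs),
                 ng_log_predictive(ng_update(q, xs), y), tolerance = 1e-10)
  }
  # spec example: chain rule equals closed form on a small batch
  expect_equal(ng_log_marginal(ng_params(m = 0, c = 1, a = 1, b = 1),
                               c(0.3, -1.2, 0.8)),
               ng_log_predictive(ng_params(0, 1, 1, 1), 0.3) +
                 ng_log_predictive(ng_update(ng_params(0, 1, 1, 1), 0.3), -1.2) +
                 ng_log_predictive(ng_update(ng_params(0, 1, 1, 1), c(0.3, -1.2)), 0.8),
               tolerance = 1e-10)
})
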