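#' Simulate a Gaussian mixture with irrelevant variables
#'
#' Generates the benchmark design used throughout the package: relevant
#' columns are drawn from a 3-component (by default) Gaussian mixture with
#' identity covariance and component means constant across relevant
#' dimensions; irrelevant columns are i.i.d. standard normal. Component
#' membership is multinomial in the mixture weights.
#'
#' Defaults reproduce the high-dimensional benchmark: mixture proportions
#' (0.5, 0.3, 0.2) centred at 0, 2 and -2 on every relevant dimension.
#'
#' @param n Number of observations.
#' @param D Total number of variables.
#' @param n_relevant Number of relevant variables (the first `n_relevant`
#'   columns). Alternatively give `relevant_fraction`.
#' @param relevant_fraction Fraction of relevant variables in (0, 1]; used
#'   when `n_relevant` is missing.
#' @param means Numeric vector of per-component means (recycled across
#'   relevant dimensions), or a `n_components x n_relevant` matrix.
#' @param weights Mixture proportions (simplex).
#' @param sds Per-component standard deviation on relevant dimensions.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `X` (`n x D` matrix), `labels` (true components),
#'   `mask` (true 0/1 relevance indicators) and the generating `spec`.
#' @examples
#' sim <- simulate_mixture(n = 100, D = 200, relevant_fraction = 0.5, seed = 1)
#' table(sim$labels)
#' @export
simulate_mixture <- function(n, D, n_relevant = NULL, relevant_fraction = NULL,
                             means = c(0, 2, -2), weights = c(0.5, 0.3, 0.2),
                             sds = 1, seed = NULL) {
  if (is.null(n_relevant)) {
    if (is.null(relevant_fraction))
      stop("give either 'n_relevant' or 'relevant_fraction'")
    stopifnot(relevant_fraction > 0, relevant_fraction <= 1)
    n_relevant <- round(relevant_fraction * D)
  }
  stopifnot(n >= 1, D >= 1, n_relevant >= 1, n_relevant <= D)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights <= 0))
    stop("'weights' must be a strictly positive simplex")
  G <- length(weights)
  if (is.matrix(means)) {
    if (nrow(means) != G || ncol(means) != n_relevant)
      stop("'means' matrix must be n_components x n_relevant")
    mu <- means
  } else {
    if (length(means) != G) stop("'means' must have one entry per component")
    mu <- matrix(means, G, n_relevant)
  }
  sds <- rep_len(sds, G)
  if (!is.null(seed)) set.seed(seed)
  labels <- sample.int(G, n, replace = TRUE, prob = weights)
  X <- matrix(stats::rnorm(n * D), n, D)
  rel <- seq_len(n_relevant)
  X[, rel] <- X[, rel] * sds[labels] + mu[labels, , drop = FALSE]
  dimnames(X) <- list(paste0("obs", seq_len(n)), paste0("var", seq_len(D)))
  list(X = X, labels = labels,
       mask = as.integer(seq_len(D) <= n_relevant),
       spec = list(n = n, D = D, n_relevant = n_relevant, means = mu,
                   weights = weights, sds = sds, seed = seed))
}

#' Simulate the small correlated-component example
#'
#' Thirty observations (by default) from a 3-component bivariate mixture:
#' two isotropic components at (2, 2) and (-3, -3) with weight 0.4 each, and
#' one component at (-3, 4) with weight 0.2 whose covariance is 2 on the
#' diagonal and 1 off-diagonal — deliberately violating the model's
#' independence assumption — plus two irrelevant standard-normal columns.
#' This is the design under which model averaging of the co-clustering
#' matrix demonstrably beats single-model selection.
#'
#' @param seed Optional integer seed.
#' @param n Number of observations (default 30).
#' @return List with `X` (`n x 4`), `labels`, `mask` (`c(1, 1, 0, 0)`).
#' @export
simulate_correlated_example <- function(seed = NULL, n = 30) {
  if (!is.null(seed)) set.seed(seed)
  weights <- c(0.4, 0.4, 0.2)
  centres <- rbind(c(2, 2), c(-3, -3), c(-3, 4))
  sigma3 <- matrix(c(2, 1, 1, 2), 2, 2)
  labels <- sample.int(3, n, replace = TRUE, prob = weights)
  rel <- matrix(0, n, 2)
  for (g in 1:2) {
    idx <- which(labels == g)
    if (length(idx))
      rel[idx, ] <- matrix(stats::rnorm(2 * length(idx)), ncol = 2) +
        matrix(centres[g, ], length(idx), 2, byrow = TRUE)
  }
  idx <- which(labels == 3)
  if (length(idx))
    rel[idx, ] <- MASS::mvrnorm(length(idx), mu = centres[3, ], Sigma = sigma3)
  X <- cbind(rel, matrix(stats::rnorm(2 * n), n, 2))
  dimnames(X) <- list(paste0("obs", seq_len(n)), paste0("var", 1:4))
  list(X = X, labels = labels, mask = c(1L, 1L, 0L, 0L),
       spec = list(n = n, weights = weights, centres = centres,
                   sigma3 = sigma3, seed = seed))
}

#' Named benchmark scenario presets
#'
#' Frozen generator settings for the package's simulation benchmarks:
#' `table1`-`table4` are 100 observations x 200 variables with 50%, 25%, 10%
#' and 5% relevant variables; `table5`-`table7` are 1000 observations x 100
#' variables with 25%, 10% and 5% relevant; `sec3_3` is the 30-observation
#' correlated-component example. All share the 3-component mixture
#' (0.5, 0.3, 0.2) at means 0, 2, -2 unless stated otherwise.
#'
#' @param name One of `"table1"` ... `"table7"`, `"sec3_3"`.
#' @param seed Optional integer seed passed to the generator.
#' @return As [simulate_mixture()] or [simulate_correlated_example()].
#' @export
scenario_preset <- function(name, seed = NULL) {
  presets <- list(
    table1 = list(n = 100, D = 200, relevant_fraction = 0.50),
    table2 = list(n = 100, D = 200, relevant_fraction = 0.25),
    table3 = list(n = 100, D = 200, relevant_fraction = 0.10),
    table4 = list(n = 100, D = 200, relevant_fraction = 0.05),
    table5 = list(n = 1000, D = 100, relevant_fraction = 0.25),
    table6 = list(n = 1000, D = 100, relevant_fraction = 0.10),
    table7 = list(n = 1000, D = 100, relevant_fraction = 0.05))
  if (identical(name, "sec3_3")) return(simulate_correlated_example(seed))
  if (!name %in% names(presets))
    stop("unknown preset; use table1..table7 or sec3_3")
  p <- presets[[name]]
  simulate_mixture(n = p$n, D = p$D, relevant_fraction = p$relevant_fraction,
                   seed = seed)
}
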