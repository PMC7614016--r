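#' Discrete grid prior for the DP concentration parameter
#'
#' The Dirichlet-process concentration parameter \eqn{\beta} controls the
#' expected number of clusters. Rather than fixing it, the greedy search
#' marginalises \eqn{\beta} over a discrete grid of permissible values with a
#' prior on the grid points; the grid posterior is updated sequentially as
#' observations are allocated.
#'
#' The default grid has 30 points log-uniformly spaced on `[0.01, 100]` with a
#' uniform prior, bracketing both few-cluster and many-cluster regimes.
#'
#' @param values Strictly positive grid values (default: log-uniform grid).
#' @param prior_weights Prior probabilities over the grid (default uniform).
#' @param L Number of grid points when `values` is not given.
#' @param range Length-2 range of the default log-uniform grid.
#' @return An object of class `"beta_grid"` with fields `values`,
#'   `prior_weights` and `posterior_weights` (initialised at the prior).
#' @examples
#' g <- beta_grid()
#' sum(g$prior_weights)
#' @export
beta_grid <- function(values = NULL, prior_weights = NULL, L = 30,
                      range = c(0.01, 100)) {
  if (is.null(values)) {
    stopifnot(length(range) == 2L, all(range > 0), range[1] < range[2], L >= 1)
    values <- if (L == 1L) sqrt(range[1] * range[2]) else
      exp(seq(log(range[1]), log(range[2]), length.out = L))
  }
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0))
    stop("grid values must be strictly positive and finite")
  L <- length(values)
  if (is.null(prior_weights)) prior_weights <- rep(1 / L, L)
  if (length(prior_weights) != L || any(prior_weights < 0))
    stop("prior weights must be a non-negative vector matching the grid")
  s <- sum(prior_weights)
  if (abs(s - 1) > 1e-8) stop("prior weights must sum to 1")
  prior_weights <- prior_weights / s
  structure(list(values = values, prior_weights = prior_weights,
                 posterior_weights = prior_weights),
            class = "beta_grid")
}

#' @export
print.beta_grid <- function(x, ...) {
  cat(sprintf("Concentration grid: %d points on [%g, %g]\n",
              length(x$values), min(x$values), max(x$values)))
  cat(sprintf("Posterior mean beta: %.4g\n",
              sum(x$values * x$posterior_weights)))
  invisible(x)
}

#' Chinese-restaurant-process allocation prior
#'
#' Conditional prior of the `i`-th allocation given the previous `i - 1`
#' allocations at a fixed concentration `beta`: probability
#' \eqn{n_k / (\beta + i - 1)} for each occupied cluster and
#' \eqn{\beta / (\beta + i - 1)} for a new cluster.
#'
#' @param counts Integer vector of occupied-cluster sizes (may be empty).
#' @param i Index of the observation being allocated (`sum(counts) == i - 1`).
#' @param beta Positive concentration value.
#' @return Probability vector of length `length(counts) + 1`; the last entry
#'   is the new-cluster probability.
#' @examples
#' crp_weights(c(2, 1), i = 4, beta = 1)  # (0.5, 0.25, 0.25)
#' @export
crp_weights <- function(counts, i, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a positive finite scalar")
  stopifnot(i >= 1, all(counts > 0) || length(counts) == 0L)
  if (sum(counts) != i - 1)
    stop("'counts' must account for the i - 1 previous observations")
  c(counts, beta) / (beta + i - 1)
}

#' Sequential update of the concentration-grid posterior
#'
#' After observation `i` is allocated to cluster `z_i`, the grid posterior is
#' updated by \eqn{\phi_l \propto \phi_l \, \pi_{i z_i l}}, where
#' \eqn{\pi_{i z_i l}} is the CRP prior probability of the chosen cluster at
#' grid value `l`.
#'
#' @param grid A [beta_grid()] object (current `posterior_weights` are used).
#' @param pi_row Vector of CRP prior probabilities of the chosen cluster, one
#'   per grid value.
#' @return The updated `"beta_grid"`.
#' @export
update_beta_posterior <- function(grid, pi_row) {
  stopifnot(inherits(grid, "beta_grid"),
            length(pi_row) == length(grid$values), all(pi_row >= 0))
  w <- grid$posterior_weights * pi_row
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("degenerate concentration-grid posterior (all weights zero)")
  grid$posterior_weights <- w / s
  grid
}

# log(sum(exp(x))) with max-shift; -Inf-safe.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
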