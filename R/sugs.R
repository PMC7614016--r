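#' Greedy sequential DP mixture clustering over random orderings
#'
#' Fits the sequential-updating-and-greedy-search model: the deterministic
#' greedy pass of [sugs_fit()] is repeated over random orderings of the
#' observations (the pass is order-dependent), and the best finished
#' partition is selected by pseudo-marginal likelihood (default, the
#' criterion recommended for plain greedy clustering because the marginal
#' likelihood tends to favour many small clusters) or marginal likelihood.
#'
#' Randomness enters only through the orderings, drawn from the session RNG;
#' call `set.seed()` beforehand for reproducible fits, or pass an explicit
#' list of orderings.
#'
#' @param X Numeric data matrix (`n x D`), observations in rows, assumed
#'   approximately standardised per column.
#' @param orderings Either the number of random orderings (default 30) or a
#'   list of explicit permutations of `1:nrow(X)`.
#' @param criterion Model-selection criterion, `"pml"` (default) or `"ml"`.
#' @param prior [ng_params()] prior for every (cluster, dimension) pair.
#' @param grid [beta_grid()] for the DP concentration parameter.
#' @param mask Optional 0/1 variable-relevance mask applied to every pass.
#' @param workers Parallel workers for the ordering loop (forked; results are
#'   independent of the worker count because all orderings are drawn first).
#' @return An object of class `"sugs"`: the selected model's `allocations`,
#'   `n_clusters` and `beta_posterior`, all per-ordering `records`
#'   ("sugs_model" objects), their `scores`, the index `best`, and the data.
#' @examples
#' sim <- simulate_mixture(n = 60, D = 5, n_relevant = 5, seed = 1)
#' set.seed(1)
#' fit <- sugs(sim$X, orderings = 5)
#' print(fit)
#' adjusted_rand_index(fit$allocations, sim$labels)
#' @seealso [sugs_varsel()] for simultaneous variable selection.
#' @export
sugs <- function(X, orderings = 30, criterion = c("pml", "ml"),
                 prior = ng_params(), grid = beta_grid(), mask = NULL,
                 workers = 1L) {
  X <- .validate_matrix(X)
  criterion <- match.arg(criterion)
  n <- nrow(X)
  ords <- if (is.list(orderings)) orderings else
    replicate(orderings, sample.int(n), simplify = FALSE)
  records <- .lapply_workers(ords, function(o)
    sugs_fit(X, o, prior = prior, grid = grid, mask = mask), workers)
  scores <- vapply(records, function(r)
    if (criterion == "pml") r$log_pml else r$log_ml, numeric(1))
  best <- which.max(scores)
  structure(list(call = match.call(), X = X, n = n, D = ncol(X),
                 records = records, scores = scores, criterion = criterion,
                 best = best, allocations = records[[best]]$allocations,
                 n_clusters = records[[best]]$n_clusters,
                 beta_posterior = records[[best]]$beta_posterior,
                 prior = prior, grid = grid,
                 mask = records[[best]]$mask),
            class = "sugs")
}

.lapply_workers <- function(xs, f, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(xs, f, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(xs, f)
  }
}

#' @export
print.sugs <- function(x, ...) {
  cat("Greedy sequential DP mixture clustering\n")
  cat(sprintf("  n = %d observations, D = %d variables, %d orderings\n",
              x$n, x$D, length(x$records)))
  cat(sprintf("  selected by %s: %d clusters (sizes: %s)\n",
              toupper(x$criterion), x$n_clusters,
              paste(sort(tabulate(x$allocations), decreasing = TRUE),
                    collapse = ", ")))
  cat(sprintf("  log ML: %.3f   log PML: %.3f\n",
              x$records[[x$best]]$log_ml, x$records[[x$best]]$log_pml))
  invisible(x)
}

#' @export
summary.sugs <- function(object, ...) {
  tab <- data.frame(
    ordering = seq_along(object$records),
    clusters = vapply(object$records, function(r) r$n_clusters, integer(1)),
    log_ml = vapply(object$records, function(r) r$log_ml, numeric(1)),
    log_pml = vapply(object$records, function(r) r$log_pml, numeric(1)))
  out <- list(n = object$n, D = object$D, criterion = object$criterion,
              best = object$best, models = tab,
              cluster_sizes = tabulate(object$allocations),
              beta_mean = sum(object$grid$values * object$beta_posterior))
  class(out) <- "summary.sugs"
  out
}

#' @export
print.summary.sugs <- function(x, ...) {
  cat(sprintf("Greedy DP clustering of %d observations (%d variables)\n",
              x$n, x$D))
  cat(sprintf("Best of %d orderings by %s (ordering %d)\n",
              nrow(x$models), toupper(x$criterion), x$best))
  cat("Cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat(sprintf("Posterior mean concentration: %.3g\n", x$beta_mean))
  cat("\nPer-ordering scores:\n")
  print(utils::head(x$models, 10))
  if (nrow(x$models) > 10) cat("...", nrow(x$models) - 10, "more orderings\n")
  invisible(x)
}

#' @describeIn sugs Posterior mean of each cluster centre (`K x D` matrix,
#'   mask-off columns reported under the global component).
#' @param object,... Method arguments.
#' @export
coef.sugs <- function(object, ...) {
  X <- object$X
  Z <- object$allocations
  prior <- object$prior
  cs <- .cluster_stats(X, Z)
  mns <- (prior$c * prior$m + cs$nk * cs$xbar) / (prior$c + cs$nk)
  rownames(mns) <- paste0("cluster", seq_len(nrow(mns)))
  colnames(mns) <- colnames(X)
  mns
}

#' @describeIn sugs Allocate new observations to the fitted clusters by
#'   posterior predictive probability (`type = "class"` gives hard labels,
#'   `"prob"` the `n x (K+1)` probability matrix whose last column is a new
#'   cluster).
#' @param newdata Matrix of new observations (defaults to the training data).
#' @param type `"class"` or `"prob"`.
#' @export
predict.sugs <- function(object, newdata = NULL, type = c("class", "prob"),
                         ...) {
  type <- match.arg(type)
  X <- object$X
  newdata <- if (is.null(newdata)) X else .validate_matrix(newdata)
  if (ncol(newdata) != ncol(X)) stop("newdata has the wrong number of columns")
  state <- cluster_state(ncol(X), object$prior)
  # rebuild cluster-by-cluster: the posterior is exchangeable in the members
  for (k in seq_len(object$n_clusters))
    for (i in which(object$allocations == k))
      state <- .state_add(state, X[i, ], k)
  grid <- object$grid
  grid$posterior_weights <- object$beta_posterior
  probs <- t(apply(newdata, 1, function(x)
    allocation_posterior(x, state, grid, object$mask)$probs))
  colnames(probs) <- c(paste0("cluster", seq_len(object$n_clusters)), "new")
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first")
}
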