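#' Posterior log-scores of one variable's relevance indicator
#'
#' Given a fixed partition, variable `d` is either relevant (its values follow
#' cluster-specific distributions) or irrelevant (a single global
#' distribution). The two unnormalised posterior log-scores are the prior
#' log-mass plus, respectively, the clustered evidence (product over clusters
#' of Normal-Gamma evidences of the within-cluster values) or the global
#' evidence of the whole column. The normalising constant is never formed:
#' comparisons stay in log space.
#'
#' @inheritParams log_marginal_likelihood
#' @param d Variable (column) index.
#' @param prior_on Prior probability that a variable is relevant, in (0, 1).
#' @return Named vector `c(on = , off = )` of unnormalised log posteriors.
#' @export
variable_log_posterior <- function(X, Z, d, prior = ng_params(),
                                   prior_on = 0.5) {
  X <- .validate_matrix(X)
  stopifnot(length(Z) == nrow(X), prior_on > 0, prior_on < 1)
  if (d < 1 || d > ncol(X)) stop("variable index out of range")
  x <- X[, d]
  on <- log(prior_on) +
    sum(vapply(split(x, Z), function(v) ng_log_marginal(prior, v), numeric(1)))
  off <- log(1 - prior_on) + ng_log_marginal(prior, x)
  c(on = on, off = off)
}

#' Greedy update of all relevance indicators
#'
#' Sets every indicator independently to the argmax of its posterior given
#' the partition (ties resolve to "on"). Vectorised over variables; the
#' global (indicator-off) evidences do not depend on the partition and may be
#' supplied precomputed.
#'
#' @inheritParams variable_log_posterior
#' @param global_evidence Optional precomputed vector of per-column global
#'   evidences (see [log_marginal_likelihood()] internals).
#' @return Integer 0/1 mask of length `ncol(X)`.
#' @export
greedy_variable_update <- function(X, Z, prior = ng_params(), prior_on = 0.5,
                                   global_evidence = NULL) {
  X <- .validate_matrix(X)
  stopifnot(length(Z) == nrow(X), prior_on > 0, prior_on < 1)
  score_on <- colSums(.cluster_evidence(X, Z, prior)) + log(prior_on)
  if (is.null(global_evidence)) global_evidence <- .global_evidence(X, prior)
  score_off <- global_evidence + log(1 - prior_on)
  as.integer(score_on >= score_off)
}

# Model score used for selection/averaging: data evidence given (Z, mask),
# optionally times the prior mass of the mask (joint model score).
.model_score <- function(log_ml, mask, prior_on, include_mask_prior = TRUE) {
  if (!include_mask_prior) return(log_ml)
  log_ml + sum(mask) * log(prior_on) + sum(1 - mask) * log(1 - prior_on)
}

#' Alternating clustering and variable selection (single ordering)
#'
#' Runs `iterations` rounds of: a fresh greedy sequential pass over the fixed
#' `ordering` using the current mask (the concentration-grid posterior
#' restarts at its prior each round), followed by a greedy update of all
#' relevance indicators given the new partition. If an update switches every
#' variable off, the previous mask is restored and iteration stops.
#' Deterministic given all inputs.
#'
#' @inheritParams sugs_fit
#' @param mask0 Initial 0/1 mask (at least one variable on).
#' @param iterations Number of alternation rounds `T` (default 2).
#' @param prior_on Prior probability a variable is relevant.
#' @return A `"sugs_model"` record with the final partition, final mask and
#'   scores (`log_ml` is the data evidence; selection among models uses
#'   [sugs_varsel()]'s joint score).
#' @export
sugsvarsel_fit <- function(X, mask0 = rep(1L, ncol(X)),
                           ordering = seq_len(nrow(X)), prior = ng_params(),
                           grid = beta_grid(), iterations = 2,
                           prior_on = 0.5, scores = TRUE) {
  X <- .validate_matrix(X)
  stopifnot(iterations >= 1)
  mask <- .validate_mask(mask0, ncol(X))
  global_evidence <- .global_evidence(X, prior)
  fit <- NULL
  for (t in seq_len(iterations)) {
    fit <- sugs_fit(X, ordering, prior = prior, grid = grid, mask = mask,
                    scores = FALSE)
    new_mask <- greedy_variable_update(X, fit$allocations, prior, prior_on,
                                       global_evidence)
    if (sum(new_mask) == 0L) break  # degenerate update: keep previous mask
    mask <- new_mask
  }
  fit$mask <- mask
  if (scores) {
    gfit <- grid
    gfit$posterior_weights <- fit$beta_posterior
    fit$log_ml <- log_marginal_likelihood(X, fit$allocations, prior, mask)
    fit$log_pml <- log_pseudo_marginal(X, fit$allocations, prior, gfit, mask)
  }
  fit
}

#' Random sub-sampling initialisation of the relevance mask
#'
#' Draws `n_subsamples` random subsets of `subsample_fraction * D` variables;
#' on each subset, runs the alternating fit over `init_orderings` random
#' orderings with an all-on initial mask, picks the best run by the marginal
#' likelihood of the sub-matrix, and extends its partition to a full-length
#' mask by a greedy indicator update over all `D` variables.
#'
#' @inheritParams sugsvarsel_fit
#' @param subsample_fraction Fraction of variables per draw, in (0, 1].
#' @param n_subsamples Number of initial masks to produce, `M`.
#' @param init_orderings Random orderings per sub-sample (default 10).
#' @return List of `M` integer 0/1 masks of length `ncol(X)`.
#' @export
subsample_initialise <- function(X, subsample_fraction = 0.1,
                                 n_subsamples = 20, init_orderings = 10,
                                 iterations = 2, prior = ng_params(),
                                 grid = beta_grid(), prior_on = 0.5) {
  X <- .validate_matrix(X)
  n <- nrow(X); D <- ncol(X)
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1,
            n_subsamples >= 1, init_orderings >= 1)
  p1 <- round(subsample_fraction * D)
  if (p1 < 2) stop("subsample_fraction * ncol(X) must be at least 2")
  global_evidence <- .global_evidence(X, prior)
  lapply(seq_len(n_subsamples), function(m) {
    vars <- sort(sample.int(D, p1))
    Xsub <- X[, vars, drop = FALSE]
    best <- NULL; best_score <- -Inf
    for (q in seq_len(init_orderings)) {
      fit <- sugsvarsel_fit(Xsub, mask0 = rep(1L, p1),
                            ordering = sample.int(n), prior = prior,
                            grid = grid, iterations = iterations,
                            prior_on = prior_on, scores = FALSE)
      sc <- .model_score(
        log_marginal_likelihood(Xsub, fit$allocations, prior, fit$mask),
        fit$mask, prior_on)
      if (sc > best_score) { best_score <- sc; best <- fit }
    }
    ext <- greedy_variable_update(X, best$allocations, prior, prior_on,
                                  global_evidence)
    if (sum(ext) == 0L) {
      # degenerate extension: fall back to the sub-sampled variables
      ext[vars] <- 1L
    }
    ext
  })
}

#' Multi-start ensemble of alternating fits
#'
#' For each initial mask, runs the alternating clustering/selection fit under
#' `orderings` fresh random orderings of the full data, returning all
#' `length(masks) * orderings` scored model records.
#'
#' @inheritParams sugsvarsel_fit
#' @param masks List of initial 0/1 masks (e.g. from
#'   [subsample_initialise()]).
#' @param orderings Random orderings per initial mask, `Q`.
#' @param include_mask_prior Include the prior mass of the mask in the
#'   reported selection score (default `TRUE`; set `FALSE` for pure data
#'   evidence).
#' @param workers Parallel workers (all random inputs are drawn before
#'   dispatch, so results do not depend on the worker count).
#' @return List of `"sugs_model"` records, each with an added `score` field.
#' @export
run_ensemble <- function(X, masks, orderings = 10, iterations = 2,
                         prior = ng_params(), grid = beta_grid(),
                         prior_on = 0.5, include_mask_prior = TRUE,
                         workers = 1L) {
  X <- .validate_matrix(X)
  stopifnot(length(masks) >= 1, orderings >= 1)
  n <- nrow(X)
  jobs <- list()
  for (m in seq_along(masks)) {
    for (q in seq_len(orderings)) {
      jobs[[length(jobs) + 1L]] <- list(mask = masks[[m]],
                                        ordering = sample.int(n))
    }
  }
  .lapply_workers(jobs, function(j) {
    fit <- sugsvarsel_fit(X, mask0 = j$mask, ordering = j$ordering,
                          prior = prior, grid = grid, iterations = iterations,
                          prior_on = prior_on, scores = TRUE)
    fit$score <- .model_score(fit$log_ml, fit$mask, prior_on,
                              include_mask_prior)
    fit
  }, workers)
}

#' Simultaneous clustering and variable selection with model averaging
#'
#' The main fitting function. Initial relevance masks are produced by the
#' random sub-sampling strategy of [subsample_initialise()]; each seeds
#' alternating clustering/variable-selection fits under fresh random
#' orderings ([run_ensemble()]); the resulting models are scored by marginal
#' likelihood (times the mask prior mass), the best model is selected, and
#' the ensemble is summarised by Occam's-window Bayesian model averaging: a
#' model-averaged co-clustering matrix, per-variable selection scores, and an
#' average-linkage consensus partition.
#'
#' Randomness (variable sub-samples and orderings) comes from the session
#' RNG; call `set.seed()` first for reproducibility.
#'
#' @inheritParams run_ensemble
#' @inheritParams subsample_initialise
#' @param criterion Score used to select the single best model: `"ml"`
#'   (default, recommended here) or `"pml"`.
#' @param occam_ratio Occam's-window ratio: models whose posterior weight is
#'   within this factor of the best are averaged (default 100).
#' @param dedup Collapse duplicate (partition, mask) models before weighting
#'   (default `TRUE`).
#' @param consensus_k,consensus_h Consensus cut: fixed number of clusters, or
#'   (default) dissimilarity height 0.5, i.e. majority co-clustering.
#' @return An object of class `"sugsvarsel"` with the best model's
#'   `allocations` and `mask`, the `ensemble` (a [model_ensemble()]), the
#'   BMA co-clustering matrix `bmac`, `variable_scores`, the `consensus`
#'   partition, and all `records`.
#' @examples
#' sim <- simulate_mixture(n = 60, D = 20, n_relevant = 10, seed = 7)
#' set.seed(7)
#' fit <- sugs_varsel(sim$X, subsample_fraction = 0.25, n_subsamples = 3,
#'                    orderings = 3, init_orderings = 3)
#' print(fit)
#' variable_recovery(fit$mask, sim$mask)
#' @export
sugs_varsel <- function(X, subsample_fraction = 0.1, n_subsamples = 20,
                        orderings = 10, init_orderings = 10, iterations = 2,
                        prior = ng_params(), grid = beta_grid(),
                        prior_on = 0.5, criterion = c("ml", "pml"),
                        occam_ratio = 100, dedup = TRUE,
                        include_mask_prior = TRUE, consensus_k = NULL,
                        consensus_h = 0.5, workers = 1L) {
  X <- .validate_matrix(X)
  criterion <- match.arg(criterion)
  masks <- subsample_initialise(X, subsample_fraction, n_subsamples,
                                init_orderings, iterations, prior, grid,
                                prior_on)
  records <- run_ensemble(X, masks, orderings, iterations, prior, grid,
                          prior_on, include_mask_prior, workers)
  sel <- vapply(records, function(r)
    if (criterion == "pml") r$log_pml else r$score, numeric(1))
  best <- which.max(sel)
  ens <- model_ensemble(records, occam_ratio = occam_ratio, dedup = dedup)
  cons <- consensus_partition(ens$bmac, k = consensus_k, h = consensus_h)
  structure(list(call = match.call(), X = X, n = nrow(X), D = ncol(X),
                 records = records, scores = sel, criterion = criterion,
                 best = best, allocations = records[[best]]$allocations,
                 mask = records[[best]]$mask,
                 n_clusters = records[[best]]$n_clusters,
                 ensemble = ens, bmac = ens$bmac,
                 variable_scores = ens$variable_scores, consensus = cons,
                 init_masks = masks, prior = prior, grid = grid,
                 prior_on = prior_on,
                 beta_posterior = records[[best]]$beta_posterior),
            class = "sugsvarsel")
}

#' @export
print.sugsvarsel <- function(x, ...) {
  cat("Greedy DP clustering with variable selection\n")
  cat(sprintf("  n = %d observations, D = %d variables, %d models explored\n",
              x$n, x$D, length(x$records)))
  cat(sprintf("  best model (%s): %d clusters, %d variables selected\n",
              toupper(x$criterion), x$n_clusters, sum(x$mask)))
  cat(sprintf("  Occam's window: %d of %d distinct models retained\n",
              length(x$ensemble$window), length(x$ensemble$weights)))
  cat(sprintf("  consensus partition: %d clusters\n", max(x$consensus)))
  invisible(x)
}

#' @export
summary.sugsvarsel <- function(object, ...) {
  out <- list(n = object$n, D = object$D,
              n_models = length(object$records),
              n_distinct = length(object$ensemble$weights),
              window_size = length(object$ensemble$window),
              best_clusters = object$n_clusters,
              best_sizes = tabulate(object$allocations),
              n_selected = sum(object$mask),
              consensus_sizes = tabulate(object$consensus),
              variable_scores = object$variable_scores,
              top_weight = max(object$ensemble$weights))
  class(out) <- "summary.sugsvarsel"
  out
}

#' @export
print.summary.sugsvarsel <- function(x, ...) {
  cat(sprintf("Clustering with variable selection: %d obs, %d variables\n",
              x$n, x$D))
  cat(sprintf("Models: %d run, %d distinct, %d in Occam's window (top weight %.3f)\n",
              x$n_models, x$n_distinct, x$window_size, x$top_weight))
  cat(sprintf("Best model: %d clusters (sizes %s), %d variables on\n",
              x$best_clusters, paste(x$best_sizes, collapse = ", "),
              x$n_selected))
  cat(sprintf("Consensus: %d clusters (sizes %s)\n",
              length(x$consensus_sizes),
              paste(x$consensus_sizes, collapse = ", ")))
  cat("BMA variable scores (summary):\n")
  print(summary(x$variable_scores))
  invisible(x)
}

#' @describeIn sugs_varsel Heatmap of the model-averaged co-clustering
#'   matrix, rows/columns ordered by the consensus dendrogram, with a
#'   consensus-cluster annotation bar.
#' @param x,... Method arguments.
#' @export
plot.sugsvarsel <- function(x, ...) {
  S <- x$bmac
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  ord <- hc$order
  n <- nrow(S)
  op <- graphics::par(mar = c(3, 3, 2, 5))
  on.exit(graphics::par(op))
  graphics::image(seq_len(n), seq_len(n), S[ord, rev(ord)],
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Model-averaged co-clustering", ...)
  cl <- x$consensus[ord]
  cols <- grDevices::hcl.colors(max(cl), "Dark 3")
  graphics::points(seq_len(n), rep(0.4, n), pch = 15, col = cols[cl],
                   xpd = NA, cex = 0.6)
  invisible(x)
}

#' @describeIn sugs_varsel Allocate new observations using the best model's
#'   partition and mask.
#' @inheritParams predict.sugs
#' @export
predict.sugsvarsel <- function(object, newdata = NULL,
                               type = c("class", "prob"), ...) {
  fake <- structure(list(X = object$X, allocations = object$allocations,
                         n_clusters = object$n_clusters, prior = object$prior,
                         grid = object$grid, mask = object$mask,
                         beta_posterior = object$beta_posterior),
                    class = "sugs")
  predict(fake, newdata = newdata, type = match.arg(type), ...)
}
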