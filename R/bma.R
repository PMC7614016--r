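#' Co-clustering matrix of a partition
#'
#' Binary `n x n` matrix whose `(i, j)` entry is 1 when observations `i` and
#' `j` share a cluster. Symmetric with unit diagonal, and invariant to
#' relabelling of the partition.
#'
#' @param Z Integer partition.
#' @return An `n x n` 0/1 matrix.
#' @examples
#' coclustering_matrix(c(1, 1, 2))
#' @export
coclustering_matrix <- function(Z) {
  stopifnot(length(Z) >= 1, all(is.finite(Z)))
  outer(Z, Z, "==") + 0
}

#' Posterior model weights from log evidences
#'
#' Softmax of per-model log scores under a uniform model prior (which
#' cancels), computed with the max-shift log-sum-exp contract. Adding a
#' constant to all scores leaves the weights unchanged.
#'
#' @param log_scores Vector of per-model log marginal likelihoods (or joint
#'   scores); at least one must be finite.
#' @return Probability vector summing to 1.
#' @export
model_weights <- function(log_scores) {
  if (!any(is.finite(log_scores)))
    stop("all model scores are -Inf: degenerate ensemble")
  w <- exp(log_scores - max(log_scores[is.finite(log_scores)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Occam's window
#'
#' Retains the models whose posterior weight is within a factor
#' `occam_ratio` of the best model's weight (the best model is always
#' retained), and renormalises the retained weights. Increasing the ratio
#' never shrinks the window.
#'
#' @param weights Probability vector of model weights.
#' @param occam_ratio Ratio `K >= 1`; the conventional range is 20-100.
#' @return List with `window` (retained indices) and `weights` (renormalised
#'   over the window).
#' @export
occam_window <- function(weights, occam_ratio = 100) {
  stopifnot(occam_ratio >= 1, all(weights >= 0))
  top <- max(weights)
  keep <- which(top <= occam_ratio * weights)
  list(window = keep, weights = weights[keep] / sum(weights[keep]))
}

#' Scored model ensemble with Occam's-window averaging
#'
#' Collects fitted model records, optionally collapses duplicate
#' (partition, mask) pairs (duplicates arise when different orderings reach
#' the same model; the posterior weights distinct models), computes posterior
#' model weights from the records' scores, forms Occam's window, and averages
#' the windowed co-clustering matrices and masks.
#'
#' @param records List of `"sugs_model"` records (with `score` fields, else
#'   `log_ml` is used).
#' @param occam_ratio See [occam_window()].
#' @param dedup Collapse duplicate models before weighting (default `TRUE`).
#' @return An object of class `"model_ensemble"`: `records` (post-dedup),
#'   `log_scores`, `weights` (over distinct models), `window`,
#'   `window_weights`, `bmac` and `variable_scores`.
#' @export
model_ensemble <- function(records, occam_ratio = 100, dedup = TRUE) {
  stopifnot(length(records) >= 1)
  scores <- vapply(records, function(r)
    if (!is.null(r$score)) r$score else r$log_ml, numeric(1))
  if (dedup) {
    key <- vapply(records, function(r)
      paste(paste(r$allocations, collapse = ","),
            paste(r$mask, collapse = ""), sep = "|"), character(1))
    keep <- !duplicated(key)
    records <- records[keep]
    scores <- scores[keep]
  }
  weights <- model_weights(scores)
  ow <- occam_window(weights, occam_ratio)
  n <- length(records[[1]]$allocations)
  S <- matrix(0, n, n)
  Fv <- numeric(length(records[[1]]$mask))
  for (j in seq_along(ow$window)) {
    r <- records[[ow$window[j]]]
    S <- S + ow$weights[j] * coclustering_matrix(r$allocations)
    Fv <- Fv + ow$weights[j] * r$mask
  }
  diag(S) <- 1
  structure(list(records = records, log_scores = scores, weights = weights,
                 occam_ratio = occam_ratio, window = ow$window,
                 window_weights = ow$weights, bmac = S,
                 variable_scores = Fv),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("Model ensemble: %d distinct models, %d in Occam's window (ratio %g)\n",
              length(x$weights), length(x$window), x$occam_ratio))
  cat(sprintf("  top model weight: %.3f\n", max(x$weights)))
  invisible(x)
}

#' Model-averaged co-clustering matrix
#'
#' The weighted average of the co-clustering matrices of the models in the
#' Occam's window, with renormalised weights: entries are posterior
#' co-clustering probabilities in `[0, 1]`, the diagonal is exactly 1, and a
#' singleton window reproduces that model's binary matrix.
#'
#' @param ensemble A [model_ensemble()].
#' @return An `n x n` matrix.
#' @export
bmac <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  ensemble$bmac
}

#' Model-averaged variable-selection scores
#'
#' Weighted average of the windowed models' relevance masks: each entry is
#' the posterior probability that the variable is relevant, a convex
#' combination of the binary indicators.
#'
#' @param ensemble A [model_ensemble()].
#' @return Numeric vector of length `D` with entries in `[0, 1]`.
#' @export
variable_bma <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  ensemble$variable_scores
}

#' Consensus partition from a co-clustering matrix
#'
#' Agglomerative average-linkage clustering on the dissimilarity
#' `1 - S`, cut either at a fixed number of clusters `k` or (default) at
#' dissimilarity height `h = 0.5`, i.e. groups whose members co-cluster in
#' the majority of the weighted ensemble. Deterministic given the matrix.
#'
#' @param S Co-clustering (similarity) matrix with entries in `[0, 1]`.
#' @param k Optional fixed number of clusters (overrides `h`).
#' @param h Dissimilarity cut height in (0, 1).
#' @return Integer partition, labels in order of first appearance.
#' @export
consensus_partition <- function(S, k = NULL, h = 0.5) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S),
            all(S >= -1e-9), all(S <= 1 + 1e-9))
  if (nrow(S) == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  # average linkage is reducible, so heights are monotone up to round-off;
  # enforce exact monotonicity for the height cut
  hc$height <- cummax(hc$height)
  cl <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  # relabel in order of first appearance for reproducible output
  as.integer(factor(cl, levels = unique(cl)))
}
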