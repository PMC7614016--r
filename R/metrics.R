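#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form):
#' 1 for identical partitions up to relabelling, approximately 0 for
#' independent random partitions; symmetric in its arguments.
#'
#' @param Z_a,Z_b Partitions of the same length (any label types).
#' @return Scalar ARI.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand_index <- function(Z_a, Z_b) {
  if (length(Z_a) != length(Z_b)) stop("partitions must have equal length")
  n <- length(Z_a)
  tab <- table(Z_a, Z_b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)  # both partitions carry no pair information
  (sij - expected) / denom
}

#' Variable-recovery proportions
#'
#' Fraction of truly relevant variables that a mask switches on, and fraction
#' of truly irrelevant variables that it switches off. An all-on mask (no
#' selection) scores (1, 0) by convention.
#'
#' @param mask Estimated 0/1 mask.
#' @param truth True 0/1 mask of the same length.
#' @return Named vector `c(relevant = , irrelevant = )`; `NA` when the truth
#'   has no variables of that kind.
#' @export
variable_recovery <- function(mask, truth) {
  if (length(mask) != length(truth)) stop("masks must have equal length")
  stopifnot(all(mask %in% 0:1), all(truth %in% 0:1))
  rel <- if (any(truth == 1)) mean(mask[truth == 1] == 1) else NA_real_
  irr <- if (any(truth == 0)) mean(mask[truth == 0] == 0) else NA_real_
  c(relevant = rel, irrelevant = irr)
}

#' Evaluate a fit against ground truth
#'
#' Convenience wrapper producing the standard report: adjusted Rand index of
#' the allocations and, when masks are given, the relevant/irrelevant
#' variable-recovery proportions.
#'
#' @param allocations Estimated partition.
#' @param labels True partition.
#' @param mask,truth_mask Optional estimated and true 0/1 masks.
#' @return List of class `"evaluation_report"`.
#' @export
evaluate_clustering <- function(allocations, labels, mask = NULL,
                                truth_mask = NULL) {
  out <- list(ari = adjusted_rand_index(allocations, labels))
  if (!is.null(mask) && !is.null(truth_mask)) {
    vr <- variable_recovery(mask, truth_mask)
    out$relevant_recovery <- unname(vr["relevant"])
    out$irrelevant_recovery <- unname(vr["irrelevant"])
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Adjusted Rand index: %.4f\n", x$ari))
  if (!is.null(x$relevant_recovery))
    cat(sprintf("Relevant variables recovered:   %.4f\n", x$relevant_recovery))
  if (!is.null(x$irrelevant_recovery))
    cat(sprintf("Irrelevant variables excluded:  %.4f\n", x$irrelevant_recovery))
  invisible(x)
}
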