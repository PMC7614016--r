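#' Normal-Gamma hyperparameters
#'
#' Constructs the conjugate Normal-Gamma prior/posterior for a single
#' Gaussian dimension with unknown mean and precision,
#' \eqn{\tau \sim \mathrm{Gamma}(a, b)}, \eqn{\mu \mid \tau \sim N(m, (c\tau)^{-1})}.
#' One instance parameterises one (cluster, dimension) pair; the same family
#' is used for the global (non-cluster-specific) component of a variable that
#' is irrelevant for clustering.
#'
#' The defaults (`m = 0`, `c = 1`, `a = 1`, `b = 1`) are the unit-information
#' prior for data standardised to mean 0 and variance 1 per column: one
#' pseudo-observation at the origin with prior mean precision 1. Its
#' posterior predictive (a Student-t with 2 degrees of freedom and squared
#' scale 2) is centred on the data scale yet heavy-tailed enough that new
#' clusters remain competitive in high dimension; substantially smaller `c`
#' makes the new-cluster predictive so diffuse that the greedy search can
#' never open a second cluster.
#'
#' @param m Prior location (real).
#' @param c Precision-scaling pseudo-count, `> 0`.
#' @param a Gamma shape, `> 0`.
#' @param b Gamma rate, `> 0`.
#' @return An object of class `"ng_params"`.
#' @examples
#' p <- ng_params()
#' ng_update(p, c(0.2, -1.1))
#' @export
ng_params <- function(m = 0, c = 1, a = 1, b = 1) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a positive finite scalar")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a positive finite scalar")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a positive finite scalar")
  structure(list(m = m, c = c, a = a, b = b), class = "ng_params")
}

#' @export
print.ng_params <- function(x, ...) {
  cat(sprintf("Normal-Gamma parameters: m = %g, c = %g, a = %g, b = %g\n",
              x$m, x$c, x$a, x$b))
  invisible(x)
}

#' Conjugate Normal-Gamma update
#'
#' Absorbs one or more observations into a Normal-Gamma prior/posterior.
#' The update is exchangeable: any ordering of sequential single-observation
#' updates equals the batch update.
#'
#' @param params An [ng_params()] object.
#' @param x Numeric vector of observations (may be empty, returning `params`
#'   unchanged).
#' @return The posterior `"ng_params"`.
#' @export
ng_update <- function(params, x) {
  stopifnot(inherits(params, "ng_params"))
  if (length(x) == 0L) return(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("observations must be finite numeric values")
  n <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  cn <- params$c + n
  ng_params(m = (params$c * params$m + n * xbar) / cn,
            c = cn,
            a = params$a + n / 2,
            b = params$b + ss / 2 +
              params$c * n * (xbar - params$m)^2 / (2 * cn))
}

#' Log posterior-predictive density
#'
#' The posterior predictive of a Normal-Gamma model is Student-t with
#' `2a` degrees of freedom, location `m` and squared scale `b(c+1)/(ac)`.
#' Vectorised over `x`.
#'
#' @param params An [ng_params()] object.
#' @param x Numeric vector of evaluation points.
#' @return Log-density values, same length as `x`.
#' @export
ng_log_predictive <- function(params, x) {
  stopifnot(inherits(params, "ng_params"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("evaluation points must be finite numeric values")
  m <- params$m; cc <- params$c; a <- params$a; b <- params$b
  z <- x - m
  lgamma(a + 0.5) - lgamma(a) -
    0.5 * log(2 * pi * b * (cc + 1) / cc) -
    (a + 0.5) * log1p(z^2 * cc / (2 * b * (cc + 1)))
}

#' Log marginal likelihood of a batch under the Normal-Gamma model
#'
#' Closed-form evidence \eqn{\int \prod_i N(x_i \mid \mu, \tau^{-1})
#' \,\mathrm{NG}(\mu, \tau) \, d\mu \, d\tau}. Equals the chain-rule sum of
#' sequential log predictive densities; the empty batch has evidence 0.
#'
#' @param prior An [ng_params()] object.
#' @param xs Numeric vector (possibly empty).
#' @return Log marginal likelihood (scalar).
#' @export
ng_log_marginal <- function(prior, xs) {
  stopifnot(inherits(prior, "ng_params"))
  n <- length(xs)
  if (n == 0L) return(0)
  if (!is.numeric(xs) || any(!is.finite(xs)))
    stop("observations must be finite numeric values")
  xbar <- mean(xs)
  ss <- sum((xs - xbar)^2)
  drop(.ng_evidence(n, xbar, ss, prior))
}

# Vectorised Normal-Gamma evidence from sufficient statistics.
# n scalar; xbar, ss vectors (or K x D matrices with n a length-K vector,
# recycled down columns). Returns log evidence with the same shape as xbar.
.ng_evidence <- function(n, xbar, ss, prior) {
  m0 <- prior$m; c0 <- prior$c; a0 <- prior$a; b0 <- prior$b
  cn <- c0 + n
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + (c0 * n / (2 * cn)) * (xbar - m0)^2
  lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(c0) - log(cn)) - (n / 2) * log(2 * pi)
}

# Per-cluster sufficient statistics of columns of X under partition Z:
# list(nk, xbar [K x D], ss [K x D]) with clusters 1..max(Z).
.cluster_stats <- function(X, Z, X2 = NULL) {
  if (is.null(X2)) X2 <- X * X
  K <- max(Z)
  nk <- tabulate(Z, nbins = K)
  S1 <- rowsum(X, Z, reorder = TRUE)
  S2 <- rowsum(X2, Z, reorder = TRUE)
  xbar <- S1 / nk
  ss <- S2 - S1^2 / nk
  ss[ss < 0] <- 0  # guard against tiny negative round-off
  list(nk = nk, xbar = xbar, ss = ss)
}
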