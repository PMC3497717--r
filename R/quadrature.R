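## One-dimensional probability quadrature rules.
##
## All rules are in the "probability" normalization: the density of the
## heterogeneous variable is absorbed into the weights, so weights sum to
## 1 and downstream code never multiplies by a density.  For the uniform
## density 1/2 on [-1,1] this makes the Gauss-Legendre weights
## w_i = 1/((1-x_i^2) P_N'(x_i)^2), i.e. half the textbook weights.

.newQuadRule <- function(kind, nodes, weights, density, seed = NULL) {
  ord <- order(nodes)
  structure(list(kind = kind, n = length(nodes), nodes = nodes[ord],
                 weights = weights[ord], density = density, seed = seed),
            class = "quadRule")
}

.checkRuleSize <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1 ||
      n != round(n))
    stop("number of nodes must be a positive integer")
  as.integer(n)
}

## Golub-Welsch: nodes and probability weights from the symmetric
## tridiagonal Jacobi matrix of an orthogonal-polynomial family.
.golubWelsch <- function(offdiag) {
  n <- length(offdiag) + 1L
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- offdiag
  J[cbind(2:n, 1:(n - 1))] <- offdiag
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  ## first-component squares are the weights normalized to the density's
  ## zeroth moment, which is 1 in the probability convention
  list(nodes = e$values[ord], weights = e$vectors[1, ord]^2)
}

## enforce the exact +/- symmetry of Gauss rules (eigen solvers leave
## O(1e-16) asymmetries; symmetrizing makes grid coincidence bitwise)
.symmetrize <- function(gw) {
  n <- length(gw$nodes)
  x <- gw$nodes; w <- gw$weights
  xs <- (x - rev(x)) / 2
  if (n %% 2 == 1) xs[(n + 1) / 2] <- 0
  ws <- (w + rev(w)) / 2
  list(nodes = xs, weights = ws / sum(ws))
}

#' Gauss-Legendre probability rule on \[-1, 1\]
#'
#' Nodes are the `n` roots of the Legendre polynomial \eqn{P_n}; weights
#' are the Gauss-Legendre weights normalized against the uniform density
#' \eqn{p(\mu) = 1/2}, so they sum to 1.  The rule integrates polynomials
#' of degree up to `2n - 1` against `p` exactly.  Nodes and weights are
#' computed by the Golub-Welsch eigenvalue method.
#'
#' @param n Number of nodes (positive integer).
#' @return A `quadRule` object with fields `kind`, `n`, `nodes`,
#'   `weights`, `density`.
#' @examples
#' r <- legendreRule(3)
#' r$nodes                      # -sqrt(3/5), 0, sqrt(3/5)
#' sum(r$weights * r$nodes^2)   # 1/3, the uniform second moment
#' @export
legendreRule <- function(n) {
  n <- .checkRuleSize(n)
  if (n == 1L) return(.newQuadRule("gauss_legendre", 0, 1, "uniform"))
  k <- 1:(n - 1)
  gw <- .symmetrize(.golubWelsch(k / sqrt(4 * k^2 - 1)))
  .newQuadRule("gauss_legendre", gw$nodes, gw$weights, "uniform")
}

#' Composite midpoint rule on \[-1, 1\]
#'
#' Uniformly spaced nodes \eqn{\mu_i = -1 + 2(i - 1/2)/n} with equal
#' weights `1/n` against the uniform density.  Second-order accurate for
#' smooth integrands; included as the "naive" finite-network
#' discretization against which the Gauss rules are compared.
#'
#' @inheritParams legendreRule
#' @return A `quadRule`.
#' @export
midpointRule <- function(n) {
  n <- .checkRuleSize(n)
  i <- seq_len(n)
  .newQuadRule("midpoint", -1 + 2 * (i - 0.5) / n, rep(1 / n, n), "uniform")
}

## probabilists' Hermite polynomial He_n via the three-term recurrence
## He_{k+1}(x) = x He_k(x) - k He_{k-1}(x); returns He_n(x)
.hermiteHe <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  hm1 <- rep(1, length(x)); h <- x
  if (n == 1) return(h)
  for (k in 1:(n - 1)) {
    hp1 <- x * h - k * hm1
    hm1 <- h; h <- hp1
  }
  h
}

#' Gauss-Hermite probability rule for the standard normal density
#'
#' Nodes are the `n` roots of the probabilists' Hermite polynomial
#' \eqn{He_n} (\eqn{He_0 = 1}, \eqn{He_1 = x}, \eqn{He_2 = x^2 - 1}, ...);
#' weights integrate against the standard normal density and sum to 1.
#' Polynomials of degree up to `2n - 1` are integrated exactly.  The
#' physicists' Hermite family (weight \eqn{e^{-x^2}}) is deliberately not
#' used anywhere in this package.
#'
#' @inheritParams legendreRule
#' @return A `quadRule`.
#' @examples
#' r <- hermiteRule(2)
#' r$nodes     # roots of x^2 - 1
#' r$weights   # 1/2, 1/2
#' @export
hermiteRule <- function(n) {
  n <- .checkRuleSize(n)
  if (n == 1L) return(.newQuadRule("gauss_hermite", 0, 1, "standard_normal"))
  gw <- .symmetrize(.golubWelsch(sqrt(1:(n - 1))))
  .newQuadRule("gauss_hermite", gw$nodes, gw$weights, "standard_normal")
}

#' Inverse-CDF (equal-probability) rule
#'
#' Nodes at the quantiles \eqn{Q^{-1}((j - 1/2)/n)} of the chosen density
#' with equal weights `1/n`: the composite midpoint rule applied after
#' transforming the integral to the unit interval by the cumulative
#' distribution function.  For the uniform density on \[-1, 1\] this
#' reproduces [midpointRule()] exactly.
#'
#' @inheritParams legendreRule
#' @param density `"standard_normal"` or `"uniform"` (on \[-1, 1\]).
#' @return A `quadRule`.
#' @export
inverseCdfRule <- function(n, density = c("standard_normal", "uniform")) {
  n <- .checkRuleSize(n)
  density <- match.arg(density)
  u <- (seq_len(n) - 0.5) / n
  nodes <- switch(density,
                  standard_normal = stats::qnorm(u),
                  uniform = -1 + 2 * u)
  .newQuadRule("inverse_cdf", nodes, rep(1 / n, n), density)
}

## evaluate expr with a private RNG stream; the caller's RNG state is
## untouched
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("an explicit integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Monte Carlo rule
#'
#' `n` independent draws from the chosen density, sorted ascending, with
#' equal weights `1/n`.  A seed is required: the same `(n, density, seed)`
#' always yields the identical rule, and the global RNG state is left
#' untouched.
#'
#' @inheritParams inverseCdfRule
#' @param seed Integer seed (required).
#' @return A `quadRule` carrying its `seed`.
#' @export
monteCarloRule <- function(n, density = c("standard_normal", "uniform"),
                           seed) {
  n <- .checkRuleSize(n)
  density <- match.arg(density)
  if (missing(seed)) stop("monteCarloRule requires an explicit seed")
  nodes <- .withSeed(seed, switch(density,
                                  standard_normal = stats::rnorm(n),
                                  uniform = stats::runif(n, -1, 1)))
  .newQuadRule("monte_carlo", nodes, rep(1 / n, n), density,
               seed = as.integer(seed))
}

#' Moment of a quadrature rule
#'
#' The rule's approximation of the `k`-th moment of its density,
#' \eqn{\sum_i w_i x_i^k}.  For Gauss rules this is exact (to rounding)
#' whenever `k <= 2n - 1`.
#'
#' @param rule A `quadRule`.
#' @param k Non-negative integer moment order.
#' @export
ruleMoment <- function(rule, k) {
  stopifnot(inherits(rule, "quadRule"), k >= 0)
  sum(rule$weights * rule$nodes^k)
}

#' @export
print.quadRule <- function(x, ...) {
  cat(sprintf("Quadrature rule: %s, %d node%s, density %s%s\n",
              x$kind, x$n, if (x$n == 1) "" else "s", x$density,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  cat(sprintf("  node range [%.6g, %.6g], weight sum %.15g\n",
              min(x$nodes), max(x$nodes), sum(x$weights)))
  invisible(x)
}
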