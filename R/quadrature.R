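# Gaussian quadrature rules built by the Golub-Welsch eigendecomposition of
# the Jacobi matrix of the orthogonal-polynomial recurrence. Weights are
# returned already normalized against the probability measure (they sum to
# 1), which keeps the generalized-Laguerre rule overflow-safe even for the
# very large Gamma shapes that arise from summed spike counts.

golub_welsch <- function(diag, offdiag) {
  n <- length(diag)
  J <- diag(diag, nrow = n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    J[cbind(idx, idx + 1)] <- offdiag
    J[cbind(idx + 1, idx)] <- offdiag
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord])^2)
}

#' Gauss-Legendre rule on the unit interval
#'
#' Nodes lie strictly inside (0, 1); weights sum to 1, so the rule
#' approximates expectations under Uniform(0, 1). Exact for polynomials of
#' degree 2n - 1.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @keywords internal
#' @noRd
gauss_unit <- function(n) {
  i <- seq_len(n - 1)
  gw <- golub_welsch(rep(0, n), i / sqrt(4 * i^2 - 1))
  list(nodes = (gw$nodes + 1) / 2, weights = gw$weights)
}

#' Gauss quadrature against a Gamma(shape, rate) density
#'
#' Generalized Gauss-Laguerre rule with alpha = shape - 1, rescaled by the
#' rate. Weights sum to 1: `sum(weights * f(nodes))` approximates
#' `E[f(lambda)]` for lambda ~ Gamma(shape, rate).
#'
#' @param n number of nodes.
#' @param shape,rate Gamma parameters (shape > 0, rate > 0).
#' @return list with `nodes` and `weights`.
#' @keywords internal
#' @noRd
gauss_gamma <- function(n, shape, rate) {
  stopifnot(shape > 0, rate > 0)
  a <- shape - 1
  i0 <- seq_len(n) - 1
  i <- seq_len(n - 1)
  gw <- golub_welsch(2 * i0 + a + 1, sqrt(i * (i + a)))
  list(nodes = gw$nodes / rate, weights = gw$weights)
}
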