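#' Model-comparison configuration
#'
#' Settings for the four-way Bayesian comparison of an AB spike-count
#' distribution against its single-stimulus A and B Poisson references.
#' The four hypotheses (with default prior 1/4 each) are:
#' \describe{
#'   \item{mixture}{each AB trial independently follows the A rate with
#'     probability alpha and the B rate otherwise, alpha ~ Uniform(0,1) —
#'     the signature of trial-to-trial fluctuation;}
#'   \item{intermediate}{all AB trials share one Poisson rate
#'     `alpha * lambda_A + (1 - alpha) * lambda_B`, alpha ~ Uniform(0,1)
#'     open at the endpoints (averaging, or sub-window switching);}
#'   \item{single}{all AB trials follow exactly one of the two
#'     single-stimulus rates, the two branches weighted 50/50
#'     (winner-take-all with a constant winner);}
#'   \item{outside}{all AB trials share a rate outside the range bounded
#'     by the two single-stimulus rates (summation or suppression), with
#'     a 50/50 mix of Uniform(0, min) and Uniform(max, cap) priors,
#'     cap = `outside_cap_multiplier * (lambda_A + lambda_B)`.}
#' }
#' The single-stimulus rates are never plugged in as point estimates:
#' they are integrated under their conjugate Gamma posteriors (prior
#' Gamma(`rate_prior_shape`, `rate_prior_rate`)) by fixed-order Gauss
#' quadrature, so results are deterministic.
#'
#' @param hypothesis_priors named or positional numeric(4) summing to 1,
#'   order mixture, intermediate, single, outside.
#' @param rate_prior_shape,rate_prior_rate Gamma prior on each Poisson
#'   mean; defaults 1/2 (Jeffreys shape) and 1e-6 (near-improper,
#'   regularized).
#' @param outside_cap_multiplier upper-prior cap as a multiple of
#'   `lambda_A + lambda_B` (default 2).
#' @param n_rate_nodes Gauss nodes per single-stimulus rate posterior
#'   (default 31).
#' @param n_alpha_nodes Gauss-Legendre nodes for alpha and for each
#'   outside branch (default 63).
#' @param fluctuation_threshold posterior probability a mixture winner
#'   must exceed (strictly) to be called fluctuating; default 0.67,
#'   i.e. mixture at least twice as likely as the other three combined.
#' @return an object of class `model_config`.
#' @export
model_config <- function(hypothesis_priors = c(mixture = 0.25,
                                               intermediate = 0.25,
                                               single = 0.25,
                                               outside = 0.25),
                         rate_prior_shape = 0.5,
                         rate_prior_rate = 1e-6,
                         outside_cap_multiplier = 2,
                         n_rate_nodes = 31L,
                         n_alpha_nodes = 63L,
                         fluctuation_threshold = 0.67) {
  hp <- as.numeric(hypothesis_priors)
  if (length(hp) != 4 || any(hp < 0) || abs(sum(hp) - 1) > 1e-8)
    stop_input("`hypothesis_priors` must be 4 non-negative values summing to 1")
  names(hp) <- hypothesis_names()
  if (rate_prior_shape <= 0) stop_input("`rate_prior_shape` must be > 0")
  if (rate_prior_rate < 0) stop_input("`rate_prior_rate` must be >= 0")
  if (outside_cap_multiplier <= 0)
    stop_input("`outside_cap_multiplier` must be > 0")
  if (!(fluctuation_threshold > 0.5 && fluctuation_threshold < 1))
    stop_input("`fluctuation_threshold` must lie in (0.5, 1)")
  structure(list(hypothesis_priors = hp,
                 rate_prior_shape = rate_prior_shape,
                 rate_prior_rate = rate_prior_rate,
                 outside_cap_multiplier = outside_cap_multiplier,
                 n_rate_nodes = as.integer(n_rate_nodes),
                 n_alpha_nodes = as.integer(n_alpha_nodes),
                 fluctuation_threshold = fluctuation_threshold),
            class = "model_config")
}

hypothesis_names <- function() c("mixture", "intermediate", "single", "outside")

#' Conjugate Gamma posterior over a Poisson mean
#'
#' With prior Gamma(shape0, rate0) and counts `x`, the posterior over the
#' per-window mean is Gamma(shape0 + sum(x), rate0 + n).
#'
#' @param counts non-negative integer vector (nonempty).
#' @param config a [model_config()] supplying the prior.
#' @return list with `shape`, `rate` and `mean` (= shape/rate).
#' @export
fit_rate_posterior <- function(counts, config = model_config()) {
  if (!is_count_vector(counts)) stop_input("`counts` must be nonempty counts")
  shape <- config$rate_prior_shape + sum(counts)
  rate <- config$rate_prior_rate + length(counts)
  list(shape = shape, rate = rate, mean = shape / rate)
}

# Poisson log-likelihood of the AB sample at scalar/vector rate mu,
# using only the sufficient statistics (S = sum, n = trials).
pois_loglik_rate <- function(mu, S, n, logfact) {
  S * log(mu) - n * mu - logfact
}

#' Log marginal likelihoods of the four hypotheses
#'
#' Computes, for one triplet, the log marginal likelihood of the AB
#' counts under each hypothesis of [model_config()], integrating over the
#' single-stimulus rate posteriors and the hypothesis-specific parameters.
#' The default `"quadrature"` method is deterministic (fixed-order Gauss
#' rules); `"montecarlo"` is an independent simple Monte Carlo integrator
#' over the same priors, useful for cross-checking the quadrature to
#' within a few hundredths of a nat at large `ndraws`.
#'
#' @param x a [triplet()].
#' @param config a [model_config()].
#' @param method `"quadrature"` (default) or `"montecarlo"`.
#' @param ndraws Monte Carlo draws (montecarlo method only).
#' @param seed RNG seed (montecarlo method only).
#' @return named numeric(4) of log marginals, with attributes
#'   `alpha_mean` (named numeric(2): posterior mean of alpha under the
#'   mixture and intermediate hypotheses) and `single_log_branches`
#'   (named numeric(2): per-branch log marginals of the single
#'   hypothesis).
#' @export
hypothesis_log_marginals <- function(x, config = model_config(),
                                     method = c("quadrature", "montecarlo"),
                                     ndraws = 1e5, seed = 1L) {
  stopifnot(inherits(x, "triplet"))
  method <- match.arg(method)
  post_a <- fit_rate_posterior(x$a_counts, config)
  post_b <- fit_rate_posterior(x$b_counts, config)
  out <- switch(method,
    quadrature = marginals_quadrature(x$ab_counts, post_a, post_b, config),
    montecarlo = marginals_montecarlo(x$ab_counts, post_a, post_b, config,
                                      ndraws = ndraws, seed = seed))
  if (any(!is.finite(out$log_marginal)))
    stop("non-finite log marginal likelihood; counts: ",
         paste(x$ab_counts, collapse = ","))
  structure(out$log_marginal,
            alpha_mean = out$alpha_mean,
            single_log_branches = out$single_log_branches)
}

marginals_quadrature <- function(ab, post_a, post_b, config) {
  n <- length(ab); S <- sum(ab); logfact <- sum(lgamma(ab + 1))
  u <- sort(unique(ab)); cnt <- as.numeric(tabulate(match(ab, u)))

  qa <- gauss_gamma(config$n_rate_nodes, post_a$shape, post_a$rate)
  qb <- gauss_gamma(config$n_rate_nodes, post_b$shape, post_b$rate)
  qu <- gauss_unit(config$n_alpha_nodes)

  nr <- config$n_rate_nodes
  ii <- rep(seq_len(nr), times = nr)   # lambda_A index over the grid
  jj <- rep(seq_len(nr), each = nr)    # lambda_B index
  la <- qa$nodes[ii]; lb <- qb$nodes[jj]
  logw <- log(qa$weights[ii]) + log(qb$weights[jj])  # sums to 0 in exp

  # per-unique-count Poisson log pmf under each rate node
  lpa <- outer(qa$nodes, u, function(l, k) stats::dpois(k, l, log = TRUE))
  lpb <- outer(qb$nodes, u, function(l, k) stats::dpois(k, l, log = TRUE))
  # expand onto the (i, j) grid, rescaled per count value for stability
  mscale <- pmax(apply(lpa, 2, max), apply(lpb, 2, max))
  PA <- exp(sweep(lpa[ii, , drop = FALSE], 2, mscale))
  PB <- exp(sweep(lpb[jj, , drop = FALSE], 2, mscale))
  scale_const <- sum(cnt * mscale)

  # ---- single: iid at lambda_A (or lambda_B), branches averaged 50/50
  m_branch_a <- logsumexp(log(qa$weights) + as.numeric(lpa %*% cnt))
  m_branch_b <- logsumexp(log(qb$weights) + as.numeric(lpb %*% cnt))
  m_single <- logsumexp(c(m_branch_a, m_branch_b)) - log(2)

  # ---- mixture and intermediate: loop over alpha nodes
  alpha <- qu$nodes; wal <- qu$weights
  k_mix <- k_int <- numeric(length(alpha))
  for (k in seq_along(alpha)) {
    a <- alpha[k]
    # mixture: sum over trials of log of the two-component pmf
    ll_mix <- as.numeric(log(a * PA + (1 - a) * PB) %*% cnt) + scale_const
    k_mix[k] <- logsumexp(logw + ll_mix)
    # intermediate: one shared rate a*la + (1-a)*lb
    mu <- a * la + (1 - a) * lb
    k_int[k] <- logsumexp(logw + pois_loglik_rate(mu, S, n, logfact))
  }
  m_mixture <- logsumexp(log(wal) + k_mix)
  m_intermediate <- logsumexp(log(wal) + k_int)
  alpha_mean <- c(
    mixture = sum(exp(log(wal) + k_mix - m_mixture) * alpha),
    intermediate = sum(exp(log(wal) + k_int - m_intermediate) * alpha))

  # ---- outside: 50/50 Uniform(0, min) and Uniform(max, cap) over the
  # shared rate, at every (lambda_A, lambda_B) node pair. The uniform
  # integral of the Poisson likelihood is an incomplete-gamma mass:
  # int_a^b l^S exp(-n l) dl = Gamma(S+1) n^-(S+1) [P(b) - P(a)],
  # evaluated in the log domain via pgamma tail probabilities.
  lo <- pmin(la, lb); hi <- pmax(la, lb)
  cap <- config$outside_cap_multiplier * (la + lb)
  lnorm <- lgamma(S + 1) - (S + 1) * log(n) - logfact
  l_low <- lnorm - log(lo) +
    stats::pgamma(lo, S + 1, rate = n, log.p = TRUE)
  l_high <- lnorm - log(cap - hi) + logspace_sub(
    stats::pgamma(hi, S + 1, rate = n, lower.tail = FALSE, log.p = TRUE),
    stats::pgamma(cap, S + 1, rate = n, lower.tail = FALSE, log.p = TRUE))
  m_out_ij <- pmax2_lse(l_low, l_high) - log(2)
  m_outside <- logsumexp(logw + m_out_ij)

  list(log_marginal = c(mixture = m_mixture, intermediate = m_intermediate,
                        single = m_single, outside = m_outside),
       alpha_mean = alpha_mean,
       single_log_branches = c(A = m_branch_a, B = m_branch_b))
}

# elementwise log(exp(a) - exp(b)) for a >= b
logspace_sub <- function(a, b) {
  out <- a + log1p(-exp(b - a))
  out[a == b] <- -Inf
  out
}

# elementwise log(exp(a) + exp(b)), tolerating -Inf
pmax2_lse <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

marginals_montecarlo <- function(ab, post_a, post_b, config, ndraws, seed) {
  n <- length(ab); S <- sum(ab); logfact <- sum(lgamma(ab + 1))
  u <- sort(unique(ab)); cnt <- as.numeric(tabulate(match(ab, u)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # stratified (Latin-hypercube) sampling of the two rate posteriors:
  # plain rgamma draws leave the tail strata that dominate the single
  # and outside marginals badly under-sampled
  u_a <- (sample.int(ndraws) - stats::runif(ndraws)) / ndraws
  u_b <- (sample.int(ndraws) - stats::runif(ndraws)) / ndraws
  la <- stats::qgamma(u_a, post_a$shape, rate = post_a$rate)
  lb <- stats::qgamma(u_b, post_b$shape, rate = post_b$rate)
  alpha <- stats::runif(ndraws)

  lpa <- outer(la, u, function(l, k) stats::dpois(k, l, log = TRUE))
  lpb <- outer(lb, u, function(l, k) stats::dpois(k, l, log = TRUE))
  mscale <- pmax(apply(lpa, 2, max), apply(lpb, 2, max))
  PA <- exp(sweep(lpa, 2, mscale)); PB <- exp(sweep(lpb, 2, mscale))

  ll_mix <- as.numeric(log(alpha * PA + (1 - alpha) * PB) %*% cnt) +
    sum(cnt * mscale)
  m_mixture <- logsumexp(ll_mix) - log(ndraws)
  w_mix <- exp(ll_mix - logsumexp(ll_mix))

  # intermediate: the inner alpha integral is likewise evaluated on a
  # midpoint grid per (lambda_A, lambda_B) draw
  Gi <- 200L
  acc_int <- acc_int_a <- rep(-Inf, ndraws)
  for (g in (seq_len(Gi) - 0.5) / Gi) {
    llg <- pois_loglik_rate(g * la + (1 - g) * lb, S, n, logfact)
    acc_int <- pmax2_lse(acc_int, llg)
    acc_int_a <- pmax2_lse(acc_int_a, llg + log(g))
  }
  m_intermediate <- logsumexp(acc_int) - log(Gi) - log(ndraws)
  alpha_mean_int <- exp(logsumexp(acc_int_a) - logsumexp(acc_int))

  ll_a <- as.numeric(lpa %*% cnt); ll_b <- as.numeric(lpb %*% cnt)
  m_branch_a <- logsumexp(ll_a) - log(ndraws)
  m_branch_b <- logsumexp(ll_b) - log(ndraws)
  m_single <- logsumexp(c(m_branch_a, m_branch_b)) - log(2)

  # outside: Monte Carlo over (lambda_A, lambda_B); the inner uniform
  # integral over lambda* is evaluated per draw on a midpoint grid (its
  # variance under naive lambda* sampling is heavy-tailed when the AB
  # counts sit between the two rates)
  lo <- pmin(la, lb); hi <- pmax(la, lb)
  cap <- config$outside_cap_multiplier * (la + lb)
  G <- 200L
  tg <- (seq_len(G) - 0.5) / G
  acc_lo <- acc_hi <- rep(-Inf, ndraws)
  for (g in tg) {
    acc_lo <- pmax2_lse(acc_lo, pois_loglik_rate(lo * g, S, n, logfact))
    acc_hi <- pmax2_lse(acc_hi,
                        pois_loglik_rate(hi + (cap - hi) * g, S, n, logfact))
  }
  per_draw <- pmax2_lse(acc_lo, acc_hi) - log(2) - log(G)
  m_outside <- logsumexp(per_draw) - log(ndraws)

  list(log_marginal = c(mixture = m_mixture, intermediate = m_intermediate,
                        single = m_single, outside = m_outside),
       alpha_mean = c(mixture = sum(w_mix * alpha),
                      intermediate = alpha_mean_int),
       single_log_branches = c(A = m_branch_a, B = m_branch_b))
}

#' Posterior probabilities from log marginals and hypothesis priors
#'
#' Softmax of `log(prior) + log marginal`, computed with log-sum-exp so
#' that widely separated marginals cannot underflow. With equal log
#' marginals and equal priors every hypothesis receives probability 1/4.
#'
#' @param log_marginals numeric vector of log marginal likelihoods.
#' @param priors prior probabilities, same length, summing to 1.
#' @return probabilities summing to 1.
#' @export
posterior_probabilities <- function(log_marginals,
                                    priors = rep(1 / length(log_marginals),
                                                 length(log_marginals))) {
  if (length(priors) != length(log_marginals))
    stop_input("`priors` must match `log_marginals` in length")
  if (abs(sum(priors) - 1) > 1e-8)
    stop_input("`priors` must sum to 1")
  lp <- log(priors) + as.numeric(log_marginals)
  tot <- logsumexp(lp)
  if (!is.finite(tot))
    stop("all hypotheses have zero marginal likelihood")
  p <- exp(lp - tot)
  names(p) <- names(log_marginals)
  p / sum(p)
}
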