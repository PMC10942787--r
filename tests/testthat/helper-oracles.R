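# Independent oracles used to validate the analytic implementations.

# Arithmetic intrinsic Bayes factor for two-Poisson-means vs shared mean,
# recomputed by a different route than the package's closed form: for each
# minimal training sample (one trial per condition), form the proper
# posterior-from-training priors and integrate the predictive marginal of
# the remaining data numerically with integrate(); then average the
# conditional Bayes factors arithmetically.
oracle_log_ibf <- function(a, b, prior_shape = 0.5) {
  lik <- function(lambda, counts) {
    vapply(lambda, function(l) prod(stats::dpois(counts, l)), numeric(1))
  }
  marg <- function(counts, shape, rate) {
    stats::integrate(function(l) lik(l, counts) *
                       stats::dgamma(l, shape, rate = rate),
                     0, Inf, rel.tol = 1e-10)$value
  }
  bfs <- numeric(0)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    rest_a <- a[-i]; rest_b <- b[-j]
    num <- marg(rest_a, prior_shape + a[i], 1) *
      marg(rest_b, prior_shape + b[j], 1)
    den <- marg(c(rest_a, rest_b), prior_shape + a[i] + b[j], 2)
    bfs <- c(bfs, num / den)
  }
  log(mean(bfs))
}

# Brute-force Pearson chi-squared statistic on a 2x2 table
oracle_pearson <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Brute-force spike counting by scanning every timestamp
oracle_count <- function(times, lo, hi) {
  n <- 0L
  for (t in times) if (t >= lo && t < hi) n <- n + 1L
  n
}

# Closed-form marginal of a single AB count under the single/mixture
# hypotheses: lambda ~ Gamma(s, r) makes the count negative binomial with
# size s and prob r / (r + 1); both hypotheses reduce to the same 50/50
# negative-binomial average when there is exactly one AB trial.
oracle_nb_point <- function(y, shape, rate) {
  stats::dnbinom(y, size = shape, prob = rate / (rate + 1))
}

# Deterministic fixed vectors for the separability example
# (ten trials near rate 20 and ten near rate 2)
fixed_a10 <- c(18L, 22L, 25L, 17L, 20L, 19L, 23L, 16L, 21L, 24L)
fixed_b10 <- c(2L, 1L, 3L, 0L, 2L, 1L, 4L, 2L, 0L, 3L)
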