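test_that("fit_rate_posterior applies the conjugate update", {
  cfg <- model_config()
  p0 <- fit_rate_posterior(c(0L, 0L, 0L), cfg)
  expect_equal(p0$shape, 0.5)
  expect_equal(p0$rate, 3, tolerance = 1e-5)
  p1 <- fit_rate_posterior(c(2L, 4L), cfg)
  expect_equal(p1$shape, 6.5)
  expect_equal(p1$rate, 2, tolerance = 1e-5)
  # shrinkage vanishes with n
  p2 <- fit_rate_posterior(rep(10L, 20), cfg)
  expect_lt(abs(p2$mean - 10), 0.1)
})

test_that("posterior_probabilities is an exact log-domain softmax", {
  p <- posterior_probabilities(rep(-12.3, 4))
  expect_equal(unname(p), rep(0.25, 4), tolerance = 1e-12)
  p2 <- posterior_probabilities(c(log(2), 0, 0, 0))
  expect_equal(unname(p2), c(0.4, 0.2, 0.2, 0.2), tolerance = 1e-12)
  # dominance limit survives in the log domain
  p3 <- posterior_probabilities(c(-1000, -1050, -1051, -1052))
  expect_gte(p3[1], 1 - 1e-20)
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  # unequal priors shift the softmax
  p4 <- posterior_probabilities(c(0, 0, 0, 0), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(unname(p4), c(0.4, 0.3, 0.2, 0.1))
  expect_error(posterior_probabilities(c(0, 0), c(0.6, 0.6)), "sum to 1")
  expect_error(posterior_probabilities(rep(-Inf, 4)), "zero marginal")
})

test_that("with one AB trial, single and mixture reduce to the same
          closed-form negative-binomial average", {
  cfg <- model_config()
  tr <- triplet(c(18L, 22L, 20L), c(4L, 6L, 5L), 12L)
  lm <- hypothesis_log_marginals(tr, cfg)
  pa <- fit_rate_posterior(tr$a_counts, cfg)
  pb <- fit_rate_posterior(tr$b_counts, cfg)
  expected <- log(0.5 * oracle_nb_point(12L, pa$shape, pa$rate) +
                  0.5 * oracle_nb_point(12L, pb$shape, pb$rate))
  expect_equal(unname(lm["single"]), expected, tolerance = 1e-6)
  expect_equal(unname(lm["mixture"]), expected, tolerance = 1e-4)
})

test_that("marginals are symmetric under A/B relabeling", {
  cfg <- model_config()
  for (s in 1:5) {
    tr <- simulate_triplet(regime_spec("mixture", seed = 200 + s,
                                       n_a = 8L, n_b = 8L, n_ab = 8L))
    sw <- triplet(tr$b_counts, tr$a_counts, tr$ab_counts)
    lm1 <- hypothesis_log_marginals(tr, cfg)
    lm2 <- hypothesis_log_marginals(sw, cfg)
    expect_equal(as.numeric(lm1), as.numeric(lm2), tolerance = 1e-8)
    f1 <- classify_triplet(tr, cfg); f2 <- classify_triplet(sw, cfg)
    expect_equal(f1$posterior, f2$posterior, tolerance = 1e-8)
    expect_false(identical(f1$single_branch, f2$single_branch))
    # alpha flips to 1 - alpha under the relabeling
    expect_equal(f1$alpha_means[["mixture"]],
                 1 - f2$alpha_means[["mixture"]], tolerance = 1e-8)
  }
})

test_that("quadrature marginals match the Monte-Carlo integrator", {
  cfg <- model_config()
  set.seed(55)
  for (s in 1:6) {
    regime <- sample(c("mixture", "intermediate", "single_A",
                       "outside_high"), 1)
    tr <- simulate_triplet(regime_spec(regime, n_a = 6L, n_b = 6L,
                                       n_ab = 6L, seed = 300 + s))
    q <- hypothesis_log_marginals(tr, cfg)
    m <- hypothesis_log_marginals(tr, cfg, method = "montecarlo",
                                  ndraws = 2e5, seed = 900 + s)
    expect_lt(max(abs(as.numeric(q) - as.numeric(m))), 0.05)
  }
})

test_that("fixed informative triplets are assigned to the right model", {
  cfg <- model_config()
  a <- c(19L, 21L, 20L, 18L, 22L, 20L, 19L, 21L, 20L, 20L)  # ~20
  b <- c(5L, 4L, 6L, 5L, 5L, 4L, 6L, 5L, 5L, 5L)            # ~5
  # interleaved values near 20 and near 5 -> mixture
  ab_mix <- c(20L, 5L, 19L, 4L, 21L, 6L, 18L, 5L, 22L, 5L)
  lm <- hypothesis_log_marginals(triplet(a, b, ab_mix), cfg)
  expect_identical(names(which.max(lm)), "mixture")
  # counts near the 12-13 midpoint -> intermediate
  ab_int <- c(12L, 13L, 12L, 13L, 12L, 13L, 12L, 12L, 13L, 13L)
  lm2 <- hypothesis_log_marginals(triplet(a, b, ab_int), cfg)
  expect_identical(names(which.max(lm2)), "intermediate")
  # counts near 25, above both rates -> outside
  ab_out <- c(25L, 26L, 24L, 25L, 27L, 25L, 24L, 26L, 25L, 25L)
  lm3 <- hypothesis_log_marginals(triplet(a, b, ab_out), cfg)
  expect_identical(names(which.max(lm3)), "outside")
  # the Monte-Carlo oracle agrees on every winner
  for (ab in list(ab_mix, ab_int, ab_out)) {
    mc <- hypothesis_log_marginals(triplet(a, b, ab), cfg,
                                   method = "montecarlo", ndraws = 1e5,
                                   seed = 77)
    expect_identical(names(which.max(mc)),
                     names(which.max(hypothesis_log_marginals(
                       triplet(a, b, ab), cfg))))
  }
})

test_that("classification flags fluctuation by the strict 0.67 rule", {
  cfg <- model_config()
  # mixture winner above the threshold
  tr <- simulate_triplet(regime_spec("mixture", seed = 11))
  f <- classify_triplet(tr, cfg)
  expect_identical(f$winner, "mixture")
  expect_true(f$fluctuating)
  expect_equal(sum(f$posterior), 1, tolerance = 1e-9)
  expect_identical(names(which.max(f$posterior)), f$winner)
  # strictness: with the threshold raised to the winner's own posterior,
  # the flag must drop (fluctuating requires strictly greater)
  thr <- min(f$winner_posterior, 1 - 1e-9)
  f_strict <- classify_triplet(tr, model_config(fluctuation_threshold = thr))
  expect_false(f_strict$fluctuating)
  # single-regime triplet recovers the generating branch
  f2 <- classify_triplet(simulate_triplet(regime_spec("single_A",
                                                      n_a = 20L, n_b = 20L,
                                                      n_ab = 20L, seed = 12)),
                         cfg)
  expect_identical(f2$winner, "single")
  expect_identical(f2$single_branch, "A")
  f3 <- classify_triplet(simulate_triplet(regime_spec("single_B",
                                                      n_a = 20L, n_b = 20L,
                                                      n_ab = 20L, seed = 12)),
                         cfg)
  expect_identical(f3$single_branch, "B")
})

test_that("determinism: identical inputs give identical quadrature fits", {
  tr <- simulate_triplet(regime_spec("mixture", seed = 8))
  f1 <- classify_triplet(tr)
  f2 <- classify_triplet(tr)
  expect_identical(f1$log_marginal, f2$log_marginal)
  expect_identical(f1$posterior, f2$posterior)
})

test_that("triplet_fit methods work", {
  tr <- simulate_triplet(regime_spec("mixture", seed = 9))
  f <- classify_triplet(tr)
  expect_output(print(f), "winner")
  expect_output(summary(f), "alpha posterior mean")
  cf <- coef(f)
  expect_true(all(c("mixture", "alpha", "lambda_A", "lambda_B") %in%
                    names(cf)))
  expect_equal(cf[["lambda_A"]], mean(tr$a_counts), tolerance = 0.2)
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "triplet")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f))
})

test_that("quadrature rules integrate Gamma and uniform moments exactly", {
  # these rules underpin every marginal; check against closed forms
  g <- spikemux:::gauss_gamma(31, shape = 300.5, rate = 15)
  expect_equal(sum(g$weights), 1, tolerance = 1e-10)
  expect_equal(sum(g$weights * g$nodes), 300.5 / 15, tolerance = 1e-8)
  expect_equal(sum(g$weights * g$nodes^2),
               (300.5 * 301.5) / 15^2, tolerance = 1e-8)
  u <- spikemux:::gauss_unit(63)
  expect_true(all(u$nodes > 0 & u$nodes < 1))
  expect_equal(sum(u$weights * u$nodes), 0.5, tolerance = 1e-12)
  expect_equal(sum(u$weights * u$nodes^5), 1 / 6, tolerance = 1e-12)
})

test_that("minority-component detectability falls with trial count", {
  frac_single <- function(n_ab) {
    mean(vapply(1:40, function(i) {
      tr <- simulate_triplet(regime_spec("mixture", alpha = 0.9,
                                         n_ab = n_ab, seed = 8100 + i))
      classify_triplet(tr)$winner == "single"
    }, logical(1)))
  }
  # a 90/10 mixture is read as single more often at the 5-trial minimum
  # than at 15 trials: with fewer trials the minority component is more
  # often absent from the sample altogether
  expect_gt(frac_single(5L), frac_single(15L))
})
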