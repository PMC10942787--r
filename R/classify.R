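#' Classify a triplet's AB response distribution
#'
#' The central fitting function: runs the four-way Bayesian model
#' comparison of [hypothesis_log_marginals()] on one triplet, applies the
#' hypothesis priors, and labels the triplet with the winning hypothesis.
#' A triplet is flagged *fluctuating* when the winner is `mixture` with
#' posterior probability strictly greater than
#' `config$fluctuation_threshold` (0.67 by default, i.e. mixture at least
#' twice as likely as the other three hypotheses combined).
#'
#' Exact posterior ties are broken deterministically in the order
#' mixture > intermediate > single > outside. The reported
#' `alpha_posterior_mean` is the posterior mean of the mixing weight
#' under the winning alpha-bearing hypothesis (mixture or intermediate);
#' when the winner carries no alpha, the mixture hypothesis' value is
#' reported. `single_branch` records which single-stimulus rate dominated
#' the single hypothesis.
#'
#' @param x a [triplet()], normally one that passed [screen_triplet()].
#' @param config a [model_config()].
#' @param method integration method, see [hypothesis_log_marginals()].
#' @param ... passed on to [hypothesis_log_marginals()].
#' @return an object of class `triplet_fit` with components
#'   `log_marginal`, `posterior` (both named over the four hypotheses),
#'   `winner`, `winner_posterior`, `fluctuating`, `alpha_posterior_mean`,
#'   `single_branch`, `triplet`, `config`.
#' @examples
#' set.seed(1)
#' tr <- simulate_triplet(regime_spec("mixture", seed = 7))
#' fit <- classify_triplet(tr)
#' fit
#' coef(fit)
#' @export
classify_triplet <- function(x, config = model_config(),
                             method = "quadrature", ...) {
  lm <- hypothesis_log_marginals(x, config, method = method, ...)
  post <- posterior_probabilities(as.numeric(lm), config$hypothesis_priors)
  names(post) <- hypothesis_names()
  # arg-max with deterministic priority on exact ties: the vector is
  # already ordered mixture, intermediate, single, outside and
  # which.max() returns the first maximum
  win <- hypothesis_names()[which.max(post)]
  wp <- unname(post[win])
  am <- attr(lm, "alpha_mean")
  branches <- attr(lm, "single_log_branches")
  structure(list(
    log_marginal = stats::setNames(as.numeric(lm), hypothesis_names()),
    posterior = post,
    winner = win,
    winner_posterior = wp,
    fluctuating = (win == "mixture" && wp > config$fluctuation_threshold),
    alpha_posterior_mean = unname(
      if (win == "intermediate") am["intermediate"] else am["mixture"]),
    alpha_means = am,
    single_branch = names(branches)[which.max(branches)],
    single_branch_posterior = unname(exp(
      max(branches) - logsumexp(as.numeric(branches)))),
    triplet = x,
    config = config), class = "triplet_fit")
}

#' @export
print.triplet_fit <- function(x, ...) {
  cat(sprintf("<triplet_fit> winner: %s (posterior %.3f)%s\n",
              x$winner, x$winner_posterior,
              if (x$fluctuating) "  [fluctuating]" else ""))
  print(round(x$posterior, 4))
  invisible(x)
}

#' @describeIn classify_triplet full per-hypothesis summary.
#' @param object a `triplet_fit`.
#' @export
summary.triplet_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Triplet classification (unit %s, pair %s)\n",
              x$triplet$unit_id, x$triplet$stimulus_pair_id))
  tab <- data.frame(log_marginal = x$log_marginal,
                    posterior = x$posterior)
  print(round(tab, 4))
  cat(sprintf("winner: %s (posterior %.4f); fluctuating: %s\n",
              x$winner, x$winner_posterior, x$fluctuating))
  cat(sprintf("alpha posterior mean: %.3f; single branch: %s (p %.3f)\n",
              x$alpha_posterior_mean, x$single_branch,
              x$single_branch_posterior))
  invisible(x)
}

#' @describeIn classify_triplet posterior probabilities, alpha mean and
#'   single-stimulus rate posterior means, as a named vector.
#' @export
coef.triplet_fit <- function(object, ...) {
  pa <- fit_rate_posterior(object$triplet$a_counts, object$config)
  pb <- fit_rate_posterior(object$triplet$b_counts, object$config)
  c(object$posterior,
    alpha = object$alpha_posterior_mean,
    lambda_A = pa$mean, lambda_B = pb$mean)
}

#' @describeIn classify_triplet draw spike-count triplets from the
#'   posterior-mean rates under the winning hypothesis (posterior
#'   predictive at the plug-in rates).
#' @param nsim number of simulated triplets.
#' @param seed RNG seed.
#' @export
simulate.triplet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  x <- object
  pa <- fit_rate_posterior(x$triplet$a_counts, x$config)
  pb <- fit_rate_posterior(x$triplet$b_counts, x$config)
  regime <- switch(x$winner,
                   mixture = "mixture", intermediate = "intermediate",
                   single = if (x$single_branch == "A") "single_A" else "single_B",
                   outside = if (mean(x$triplet$ab_counts) >
                                   max(pa$mean, pb$mean))
                     "outside_high" else "outside_low")
  base_seed <- if (is.null(seed)) 1L else as.integer(seed)
  lapply(seq_len(nsim), function(i) simulate_triplet(regime_spec(
    regime, lambda_a = pa$mean, lambda_b = pb$mean,
    alpha = max(0.01, min(0.99, x$alpha_posterior_mean)),
    n_a = length(x$triplet$a_counts), n_b = length(x$triplet$b_counts),
    n_ab = length(x$triplet$ab_counts), seed = child_seed(base_seed, i))))
}

#' @describeIn classify_triplet spike-count histograms of the three
#'   conditions with display smoothing ([smooth_count_histogram()]) of
#'   the AB distribution and the single-stimulus posterior-mean rates as
#'   dashed lines.
#' @export
plot.triplet_fit <- function(x, ...) {
  tr <- x$triplet
  kmax <- max(tr$a_counts, tr$b_counts, tr$ab_counts) + 2
  h <- tabulate(tr$ab_counts + 1, nbins = kmax + 1)
  sm <- smooth_count_histogram(h)
  graphics::barplot(h, names.arg = 0:kmax, col = "grey85", border = NA,
                    xlab = "spike count / window", ylab = "AB trials",
                    main = sprintf("winner: %s (p = %.2f)", x$winner,
                                   x$winner_posterior), ...)
  # barplot x-coordinates are 0.2 + 1.2*k + 0.5 for bin k
  graphics::lines(0.7 + 1.2 * sm$x, sm$y, lwd = 2)
  pa <- fit_rate_posterior(tr$a_counts, x$config)
  pb <- fit_rate_posterior(tr$b_counts, x$config)
  graphics::abline(v = 0.7 + 1.2 * pa$mean, col = "red", lty = 2)
  graphics::abline(v = 0.7 + 1.2 * pb$mean, col = "blue", lty = 2)
  invisible(x)
}

#' Classify many triplets into a tabular report
#'
#' @param triplets a list of [triplet()] objects.
#' @param config a [model_config()].
#' @param ... passed on to [classify_triplet()].
#' @return a data.frame with one row per triplet: identifiers, the four
#'   log marginals and posteriors, winner, winner posterior, fluctuating
#'   flag and alpha posterior mean.
#' @export
classify_triplets <- function(triplets, config = model_config(), ...) {
  if (!length(triplets)) {
    return(data.frame(unit_id = character(0),
                      stimulus_pair_id = character(0),
                      lm_mixture = numeric(0), lm_intermediate = numeric(0),
                      lm_single = numeric(0), lm_outside = numeric(0),
                      p_mixture = numeric(0), p_intermediate = numeric(0),
                      p_single = numeric(0), p_outside = numeric(0),
                      winner = character(0), winner_posterior = numeric(0),
                      fluctuating = logical(0),
                      alpha_posterior_mean = numeric(0),
                      single_branch = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(triplets, function(tr) {
    f <- classify_triplet(tr, config, ...)
    data.frame(unit_id = tr$unit_id, stimulus_pair_id = tr$stimulus_pair_id,
               lm_mixture = f$log_marginal["mixture"],
               lm_intermediate = f$log_marginal["intermediate"],
               lm_single = f$log_marginal["single"],
               lm_outside = f$log_marginal["outside"],
               p_mixture = f$posterior["mixture"],
               p_intermediate = f$posterior["intermediate"],
               p_single = f$posterior["single"],
               p_outside = f$posterior["outside"],
               winner = f$winner,
               winner_posterior = f$winner_posterior,
               fluctuating = f$fluctuating,
               alpha_posterior_mean = f$alpha_posterior_mean,
               single_branch = f$single_branch,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
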