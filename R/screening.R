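#' Fano factor (variance-to-mean ratio) of spike counts
#'
#' Unbiased (n - 1) sample variance divided by the sample mean. A Poisson
#' response has Fano factor ~1; values well above 1 indicate
#' overdispersion. For an all-zero vector the ratio is undefined and
#' `Inf` is returned so that downstream screens fail such units.
#'
#' @param counts vector of non-negative integers, length >= 2.
#' @return a non-negative real, possibly `Inf`.
#' @examples
#' fano_factor(c(0, 2, 4))   # variance 4, mean 2 -> 2
#' @export
fano_factor <- function(counts) {
  if (!is_count_vector(counts) || length(counts) < 2)
    stop_input("`counts` must hold at least two non-negative integers")
  m <- mean(counts)
  if (m == 0) return(Inf)
  stats::var(counts) / m
}

# Log marginal likelihood of iid Poisson counts under the (improper for
# prior_rate = 0) Gamma(prior_shape, prior_rate) rate prior, dropping the
# 1/prod(x!) factor, which always cancels between hypotheses on the same
# data: log Gamma(s + S) - (s + S) log(r + n) - [log Gamma(s) - s log r].
# The bracketed normalizer is omitted too (cancels inside the intrinsic
# construction).
poisson_lmarg_kernel <- function(S, n, prior_shape, prior_rate = 0) {
  lgamma(prior_shape + S) - (prior_shape + S) * log(prior_rate + n)
}

#' Separability of two Poisson samples by intrinsic Bayes factor
#'
#' Natural-log arithmetic intrinsic Bayes factor for the hypothesis that
#' two spike-count samples come from Poisson distributions with distinct
#' means, against a single shared mean. The improper Jeffreys-type
#' Gamma(`prior_shape`, 0) rate prior is made proper by conditioning on
#' minimal training samples (one trial from each sample), and the partial
#' Bayes factors are averaged arithmetically over all such pairs. Positive
#' values favor distinct means; the statistic is symmetric in its two
#' arguments.
#'
#' @param a_counts,b_counts non-negative integer vectors (nonempty).
#' @param prior_shape shape of the reference Gamma rate prior
#'   (default 1/2, the Jeffreys choice for a Poisson mean).
#' @return log intrinsic Bayes factor (natural log).
#' @seealso [separability_posterior()] to convert to a posterior
#'   probability at given prior odds.
#' @export
log_ibf_separability <- function(a_counts, b_counts, prior_shape = 0.5) {
  if (!is_count_vector(a_counts) || !is_count_vector(b_counts))
    stop_input("both count vectors must be nonempty non-negative integers")
  na <- length(a_counts); nb <- length(b_counts)
  Sa <- sum(a_counts); Sb <- sum(b_counts)
  # full-data Bayes factor under the (unnormalized) reference prior
  lbf10_full <- poisson_lmarg_kernel(Sa, na, prior_shape) +
    poisson_lmarg_kernel(Sb, nb, prior_shape) -
    poisson_lmarg_kernel(Sa + Sb, na + nb, prior_shape)
  # correction: average over minimal training samples (x_i, y_j) of
  # BF01 on the training sample alone
  x <- rep(a_counts, times = nb)
  y <- rep(b_counts, each = na)
  lbf01_train <- poisson_lmarg_kernel(x + y, 2, prior_shape) -
    poisson_lmarg_kernel(x, 1, prior_shape) -
    poisson_lmarg_kernel(y, 1, prior_shape)
  lbf10_full + (logsumexp(lbf01_train) - log(length(lbf01_train)))
}

#' Posterior probability of distinct Poisson means
#'
#' Converts a log Bayes factor for "distinct means" into a posterior
#' probability under the given prior odds (default 1, a 50-50 chance).
#' At `log_bf = 3` and even odds this evaluates to ~0.953, which is why a
#' log-intrinsic-Bayes-factor threshold of 3 corresponds to at least 95%
#' likelihood that the two samples are separable.
#'
#' @param log_bf natural-log Bayes factor favoring distinct means.
#' @param prior_odds prior odds of distinct vs shared mean.
#' @return probability in (0, 1).
#' @export
separability_posterior <- function(log_bf, prior_odds = 1) {
  stats::plogis(log_bf + log(prior_odds))
}

#' Screening configuration
#'
#' The three triplet inclusion criteria: a minimum number of trials in
#' each of the A, B and AB conditions; a ceiling on the average of the A
#' and B Fano factors (triplets are discarded when the mean
#' variance-to-mean ratio exceeds `max_mean_fano`, so exactly 3 is
#' retained under the default); and a floor on the log intrinsic Bayes
#' factor separating the A and B count distributions (strictly greater
#' than `min_log_ibf_separation`, i.e. at least ~95% likelihood of
#' distinct Poisson means at even prior odds).
#'
#' @param min_trials minimum trials per condition (default 5).
#' @param max_mean_fano Fano ceiling (default 3; stricter variant 2).
#' @param min_log_ibf_separation separability floor, natural log
#'   (default 3).
#' @param separation_prior_odds prior odds used when reporting the
#'   separability posterior (default 1).
#' @return an object of class `screening_config`.
#' @export
screening_config <- function(min_trials = 5L, max_mean_fano = 3,
                             min_log_ibf_separation = 3,
                             separation_prior_odds = 1) {
  if (min_trials < 1) stop_input("`min_trials` must be >= 1")
  if (!is.finite(max_mean_fano) || max_mean_fano <= 0)
    stop_input("`max_mean_fano` must be > 0")
  if (!is.finite(min_log_ibf_separation))
    stop_input("`min_log_ibf_separation` must be finite")
  structure(list(min_trials = as.integer(min_trials),
                 max_mean_fano = max_mean_fano,
                 min_log_ibf_separation = min_log_ibf_separation,
                 separation_prior_odds = separation_prior_odds),
            class = "screening_config")
}

#' Screen one triplet against the inclusion criteria
#'
#' Evaluates all three criteria and records every failure (not just the
#' first): `trials` (any condition below `min_trials`), `fano` (mean of
#' the A and B Fano factors above `max_mean_fano`, or undefined), and
#' `separability` (log intrinsic Bayes factor not above the floor).
#'
#' @param x a [triplet()].
#' @param config a [screening_config()].
#' @return an object of class `screening_report`: a list with the trial
#'   counts, `fano_a`, `fano_b`, `mean_fano`, `log_ibf_separation`,
#'   `included` and `failure_reasons`.
#' @export
screen_triplet <- function(x, config = screening_config()) {
  stopifnot(inherits(x, "triplet"), inherits(config, "screening_config"))
  n_a <- length(x$a_counts); n_b <- length(x$b_counts)
  n_ab <- length(x$ab_counts)
  fano_a <- if (n_a >= 2) fano_factor(x$a_counts) else Inf
  fano_b <- if (n_b >= 2) fano_factor(x$b_counts) else Inf
  mean_fano <- (fano_a + fano_b) / 2
  libf <- log_ibf_separability(x$a_counts, x$b_counts)
  reasons <- character(0)
  if (min(n_a, n_b, n_ab) < config$min_trials) reasons <- c(reasons, "trials")
  if (!(mean_fano <= config$max_mean_fano)) reasons <- c(reasons, "fano")
  if (!(libf > config$min_log_ibf_separation))
    reasons <- c(reasons, "separability")
  structure(list(unit_id = x$unit_id, stimulus_pair_id = x$stimulus_pair_id,
                 n_a = n_a, n_b = n_b, n_ab = n_ab,
                 fano_a = fano_a, fano_b = fano_b, mean_fano = mean_fano,
                 log_ibf_separation = libf,
                 separation_posterior = separability_posterior(
                   libf, config$separation_prior_odds),
                 included = length(reasons) == 0,
                 failure_reasons = reasons),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %s\n",
              if (x$included) "INCLUDED" else
                paste("excluded:", paste(x$failure_reasons, collapse = ", "))))
  cat(sprintf("  trials A/B/AB: %d/%d/%d   mean Fano: %.3g   log IBF: %.3g\n",
              x$n_a, x$n_b, x$n_ab, x$mean_fano, x$log_ibf_separation))
  invisible(x)
}

#' Screen many triplets into a tabular report
#'
#' @param triplets a list of [triplet()] objects.
#' @param config a [screening_config()].
#' @return a data.frame with one row per triplet and the fields of
#'   [screen_triplet()] (failure reasons collapsed to a `;`-separated
#'   string).
#' @export
screen_triplets <- function(triplets, config = screening_config()) {
  rows <- lapply(triplets, function(tr) {
    r <- screen_triplet(tr, config)
    data.frame(unit_id = r$unit_id, stimulus_pair_id = r$stimulus_pair_id,
               n_a = r$n_a, n_b = r$n_b, n_ab = r$n_ab,
               fano_a = r$fano_a, fano_b = r$fano_b,
               mean_fano = r$mean_fano,
               log_ibf_separation = r$log_ibf_separation,
               included = r$included,
               failure_reasons = paste(r$failure_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
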