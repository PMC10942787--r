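regime_names <- function() c("mixture", "intermediate", "single_A",
                             "single_B", "outside_high", "outside_low",
                             "mid_trial_switch")

#' Specification of a synthetic response regime
#'
#' Describes one ground-truth triplet: the single-stimulus per-window
#' expected counts, the AB generating regime, the mixing weight used by
#' the mixture and intermediate regimes, trial counts per condition, an
#' overdispersion level for the single-stimulus counts, and a seed.
#'
#' Defaults mirror the reference conditions used throughout the package:
#' well-separated rates of 20 and 5 expected counts per 200 ms window
#' (100 and 25 Hz), alpha = 0.5, 15 trials per condition, Poisson
#' dispersion. AB counts are generated per regime:
#' \describe{
#'   \item{mixture}{each trial flips an alpha-coin between Poisson
#'     draws at `lambda_a` and `lambda_b`;}
#'   \item{intermediate}{Poisson at `alpha*lambda_a + (1-alpha)*lambda_b`;}
#'   \item{single_A / single_B}{Poisson at that single rate;}
#'   \item{outside_high}{Poisson at `lambda_a + lambda_b` (summation);}
#'   \item{outside_low}{Poisson at `0.25 * min(lambda_a, lambda_b)`
#'     (strong suppression);}
#'   \item{mid_trial_switch}{each trial is the sum of one half-window
#'     draw at each rate — the within-trial switching caveat case.}
#' }
#'
#' @param regime one of the regime names above.
#' @param lambda_a,lambda_b expected counts per window (> 0).
#' @param alpha mixing weight in (0, 1).
#' @param n_a,n_b,n_ab trials per condition (>= 1).
#' @param dispersion variance-to-mean ratio of the A and B counts; 1
#'   draws Poisson, > 1 draws a mean/Fano-matched negative binomial.
#' @param outside_low_multiplier,outside_high_rate overrides for the two
#'   outside anchors (defaults 0.25 and `lambda_a + lambda_b`).
#' @param seed RNG seed for reproducibility.
#' @return an object of class `regime_spec`.
#' @export
regime_spec <- function(regime = regime_names(),
                        lambda_a = 20, lambda_b = 5, alpha = 0.5,
                        n_a = 15L, n_b = 15L, n_ab = 15L,
                        dispersion = 1,
                        outside_low_multiplier = 0.25,
                        outside_high_rate = NULL,
                        seed = 1L) {
  regime <- match.arg(regime)
  if (!(lambda_a > 0 && lambda_b > 0)) stop_input("rates must be > 0")
  if (!(alpha > 0 && alpha < 1)) stop_input("`alpha` must lie in (0, 1)")
  if (min(n_a, n_b, n_ab) < 1) stop_input("trial counts must be >= 1")
  if (dispersion < 1) stop_input("`dispersion` must be >= 1")
  structure(list(regime = regime, lambda_a = lambda_a, lambda_b = lambda_b,
                 alpha = alpha, n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_ab = as.integer(n_ab), dispersion = dispersion,
                 outside_low_multiplier = outside_low_multiplier,
                 outside_high_rate = outside_high_rate %||%
                   (lambda_a + lambda_b),
                 seed = as.integer(seed)),
            class = "regime_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean/Fano-matched count draws: Poisson at fano = 1, else negative
# binomial with size = mean/(fano-1), which has variance fano * mean
draw_counts <- function(n, mean, fano = 1) {
  if (fano <= 1 + 1e-12) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = mean / (fano - 1), mu = mean)
}

#' Simulate one ground-truth triplet
#'
#' @param spec a [regime_spec()].
#' @return a [triplet()] whose `regime_spec` attribute carries the
#'   generating spec. Identical specs (including seed) give identical
#'   triplets.
#' @export
simulate_triplet <- function(spec) {
  stopifnot(inherits(spec, "regime_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  a <- draw_counts(spec$n_a, spec$lambda_a, spec$dispersion)
  b <- draw_counts(spec$n_b, spec$lambda_b, spec$dispersion)
  ab <- switch(spec$regime,
    mixture = {
      pick_a <- stats::runif(spec$n_ab) < spec$alpha
      ifelse(pick_a, stats::rpois(spec$n_ab, spec$lambda_a),
             stats::rpois(spec$n_ab, spec$lambda_b))
    },
    intermediate = stats::rpois(
      spec$n_ab, spec$alpha * spec$lambda_a + (1 - spec$alpha) * spec$lambda_b),
    single_A = stats::rpois(spec$n_ab, spec$lambda_a),
    single_B = stats::rpois(spec$n_ab, spec$lambda_b),
    outside_high = stats::rpois(spec$n_ab, spec$outside_high_rate),
    outside_low = stats::rpois(
      spec$n_ab, spec$outside_low_multiplier * min(spec$lambda_a,
                                                   spec$lambda_b)),
    mid_trial_switch = stats::rpois(spec$n_ab, spec$lambda_a / 2) +
      stats::rpois(spec$n_ab, spec$lambda_b / 2))
  out <- triplet(a, b, ab,
                 unit_id = paste0("sim_", spec$regime, "_", spec$seed),
                 stimulus_pair_id = "A+B")
  attr(out, "regime_spec") <- spec
  out
}

#' Simulate a labeled population of triplets
#'
#' One triplet per spec. Each spec's seed is re-derived from the master
#' seed and the spec's position by a counter-based rule, so extending
#' the spec list never perturbs earlier triplets.
#'
#' @param specs list of [regime_spec()] objects.
#' @param master_seed integer master seed.
#' @return an object of class `ground_truth_dataset`: list with
#'   `triplets`, `specs` (seeds rewritten), and `composition` (regime
#'   frequency table).
#' @export
simulate_population <- function(specs, master_seed = 1L) {
  if (!length(specs)) stop_input("`specs` must be nonempty")
  specs <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "regime_spec"))
    sp$seed <- child_seed(master_seed, i)
    sp
  })
  triplets <- lapply(specs, simulate_triplet)
  comp <- table(factor(vapply(specs, `[[`, character(1), "regime"),
                       levels = regime_names()))
  structure(list(triplets = triplets, specs = specs, composition = comp),
            class = "ground_truth_dataset")
}

#' @export
print.ground_truth_dataset <- function(x, ...) {
  cat(sprintf("<ground_truth_dataset> %d triplets\n", length(x$triplets)))
  print(x$composition[x$composition > 0])
  invisible(x)
}

#' Overdispersed spike counts at a target Fano factor
#'
#' Negative-binomial counts with mean `lambda` and variance-to-mean
#' ratio `target_fano`; `target_fano = 1` reduces to Poisson. Used to
#' build units the Fano screen must reject.
#'
#' @param lambda mean count per window.
#' @param target_fano desired variance-to-mean ratio, >= 1.
#' @param n number of trials.
#' @param seed RNG seed.
#' @return integer vector of counts.
#' @export
make_overdispersed_unit <- function(lambda, target_fano, n, seed = 1L) {
  if (!(target_fano >= 1)) stop_input("`target_fano` must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  draw_counts(n, lambda, target_fano)
}

#' Flatten a ground-truth dataset to the tabular trial format
#'
#' Produces the trial data.frame dialect that [read_trials()] /
#' [build_triplets()] consume, so synthetic data can exercise the whole
#' pipeline including I/O. Stimulus identifiers encode the generating
#' unit; all trials are marked correct.
#'
#' @param dataset a [simulate_population()] result (or a list of
#'   triplets).
#' @return a trial data.frame with columns `unit_id`, `trial_id`,
#'   `condition`, `stimulus_a_id`, `stimulus_b_id`, `correct`,
#'   `spike_count`.
#' @export
as_trials <- function(dataset) {
  triplets <- if (inherits(dataset, "ground_truth_dataset"))
    dataset$triplets else dataset
  rows <- lapply(seq_along(triplets), function(i) {
    tr <- triplets[[i]]
    uid <- if (!is.na(tr$unit_id)) tr$unit_id else paste0("unit", i)
    n <- c(length(tr$a_counts), length(tr$b_counts), length(tr$ab_counts))
    data.frame(
      unit_id = uid,
      trial_id = sprintf("%s_t%03d", uid, seq_len(sum(n))),
      condition = rep(c("A", "B", "AB"), n),
      stimulus_a_id = paste0(uid, "_sA"),
      stimulus_b_id = paste0(uid, "_sB"),
      correct = TRUE,
      spike_count = c(tr$a_counts, tr$b_counts, tr$ab_counts),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
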