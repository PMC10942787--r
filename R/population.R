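#' Tally classifications into response categories
#'
#' Counts, for one stimulus regime, how many triplets were classified
#' into each of the four categories. A triplet contributes to its
#' winner's category when `winner_posterior >= threshold` (the display
#' convention "0.67 or greater"); otherwise it counts as unclassified.
#'
#' @param classifications a data.frame from [classify_triplets()] or a
#'   list of `triplet_fit` objects.
#' @param threshold minimum winner posterior for a confident
#'   classification, in (0, 1]; 0 classifies everything.
#' @param regime optional label for the stimulus regime.
#' @param n_screened_out optional count of triplets that never reached
#'   classification, carried for attrition reporting.
#' @return an object of class `category_tally`: list with `regime`,
#'   `counts` (named numeric over mixture/intermediate/single/outside),
#'   `n_unclassified`, `n_screened_out`.
#' @export
tally_classifications <- function(classifications, threshold = 0.67,
                                  regime = NA_character_,
                                  n_screened_out = 0L) {
  if (!(threshold >= 0 && threshold <= 1))
    stop_input("`threshold` must lie in [0, 1]")
  if (is.data.frame(classifications)) {
    winner <- classifications$winner
    wp <- classifications$winner_posterior
  } else {
    winner <- vapply(classifications, `[[`, character(1), "winner")
    wp <- vapply(classifications, `[[`, numeric(1), "winner_posterior")
  }
  counts <- stats::setNames(numeric(4), hypothesis_names())
  ok <- wp >= threshold
  if (any(ok)) {
    t0 <- table(factor(winner[ok], levels = hypothesis_names()))
    counts[] <- as.numeric(t0)
  }
  structure(list(regime = regime, counts = counts,
                 n_unclassified = sum(!ok),
                 n_screened_out = as.integer(n_screened_out),
                 threshold = threshold),
            class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  cat(sprintf("<category_tally> regime: %s (threshold %.2f)\n",
              x$regime, x$threshold))
  print(x$counts)
  cat(sprintf("  unclassified: %d   screened out: %d\n",
              x$n_unclassified, x$n_screened_out))
  invisible(x)
}

#' @describeIn tally_classifications stacked-bar display of the category
#'   counts.
#' @param x a `category_tally`.
#' @export
plot.category_tally <- function(x, ...) {
  graphics::barplot(cbind(x$counts), beside = FALSE,
                    col = c("black", "grey40", "grey70", "white"),
                    legend.text = names(x$counts),
                    ylab = "classified triplets",
                    main = paste("regime:", x$regime), ...)
  invisible(x)
}

#' Proportion of mixture classifications
#'
#' Mixture count divided by the total of confidently classified triplets
#' (unclassified triplets are excluded from the denominator).
#'
#' @param tally a [tally_classifications()] result.
#' @return a proportion in [0, 1].
#' @export
mixture_proportion <- function(tally) {
  stopifnot(inherits(tally, "category_tally"))
  tot <- sum(tally$counts)
  if (tot == 0) stop_input("no classified triplets; proportion undefined")
  unname(tally$counts["mixture"] / tot)
}

#' Compare mixture prevalence between two regimes
#'
#' Pearson chi-squared test (1 degree of freedom, no continuity
#' correction by default) on the 2x2 table of mixture vs non-mixture
#' classifications across two regimes.
#'
#' @param tally_1,tally_2 [tally_classifications()] results with at
#'   least one classified triplet each.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return an object of class `prevalence_comparison`: list with
#'   `statistic`, `dof`, `p_value` and the 2x2 `contingency` table
#'   (rows = regimes, columns = mixture / non-mixture).
#' @export
compare_mixture_prevalence <- function(tally_1, tally_2, correct = FALSE) {
  stopifnot(inherits(tally_1, "category_tally"),
            inherits(tally_2, "category_tally"))
  row1 <- c(tally_1$counts["mixture"], sum(tally_1$counts) -
              tally_1$counts["mixture"])
  row2 <- c(tally_2$counts["mixture"], sum(tally_2$counts) -
              tally_2$counts["mixture"])
  tab <- rbind(row1, row2)
  dimnames(tab) <- list(regime = c(as.character(tally_1$regime),
                                   as.character(tally_2$regime)),
                        category = c("mixture", "non_mixture"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_input("degenerate contingency table (a zero row or column)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(statistic = unname(ct$statistic),
                 dof = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 contingency = tab,
                 # asymptotic p-values are approximate with sparse cells
                 expected_small = any(ct$expected < 5)),
            class = "prevalence_comparison")
}

#' @export
print.prevalence_comparison <- function(x, ...) {
  cat(sprintf("<prevalence_comparison> X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  print(x$contingency)
  invisible(x)
}

#' Smooth a spike-count histogram for display
#'
#' Convolves the histogram with the normalized 3-point kernel
#' (1/4, 1/2, 1/4) — the middle point weighted twice as much as either
#' outer point — replicating the edge bins, then interpolates the result
#' with a cubic spline onto a finer grid. Intended purely for display;
#' all statistics operate on raw counts.
#'
#' @param histogram numeric vector of non-negative bin heights (bin `i`
#'   holds the frequency of spike count `i - 1`).
#' @param n_out number of points on the interpolated grid.
#' @param edge `"replicate"` (default) pads with copies of the edge
#'   bins; `"zero"` pads with zeros.
#' @return list with `x` (count-scale positions on the fine grid), `y`
#'   (interpolated curve) and `smoothed` (the kernel-stage bin values).
#'   Histograms shorter than 3 bins are returned unsmoothed with a
#'   warning.
#' @export
smooth_count_histogram <- function(histogram, n_out = 10 * length(histogram),
                                   edge = c("replicate", "zero")) {
  edge <- match.arg(edge)
  h <- as.numeric(histogram)
  if (any(!is.finite(h)) || any(h < 0))
    stop_input("`histogram` must be finite and non-negative")
  x <- seq_along(h) - 1
  if (length(h) < 3) {
    warning("histogram shorter than 3 bins; returned unsmoothed")
    sp <- stats::spline(x, h, n = n_out)
    return(list(x = sp$x, y = sp$y, smoothed = h))
  }
  pad <- switch(edge, replicate = c(h[1], h, h[length(h)]), zero = c(0, h, 0))
  k <- length(h)
  sm <- 0.25 * pad[seq_len(k)] + 0.5 * pad[seq_len(k) + 1] +
    0.25 * pad[seq_len(k) + 2]
  sp <- stats::spline(x, sm, n = n_out)
  list(x = sp$x, y = sp$y, smoothed = sm)
}
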