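#' Construct a triplet of matched spike-count conditions
#'
#' A triplet holds the spike counts of one unit for a fixed stimulus pair
#' under the three conditions of interest: stimulus A alone, stimulus B
#' alone, and both together (AB). The A/B labels are arbitrary but must be
#' consistent across the three vectors.
#'
#' @param a_counts,b_counts,ab_counts non-negative integer vectors, one
#'   entry per included trial.
#' @param unit_id,stimulus_pair_id optional identifiers carried through
#'   reports.
#' @return an object of class `triplet`.
#' @examples
#' tr <- triplet(c(18, 22, 19), c(4, 6, 5), c(20, 5, 21))
#' tr
#' @export
triplet <- function(a_counts, b_counts, ab_counts,
                    unit_id = NA_character_,
                    stimulus_pair_id = NA_character_) {
  for (nm in c("a_counts", "b_counts", "ab_counts")) {
    v <- get(nm)
    if (!is_count_vector(v))
      stop_input("`", nm, "` must be a nonempty vector of non-negative integers")
  }
  structure(list(a_counts = as.integer(a_counts),
                 b_counts = as.integer(b_counts),
                 ab_counts = as.integer(ab_counts),
                 unit_id = as.character(unit_id),
                 stimulus_pair_id = as.character(stimulus_pair_id)),
            class = "triplet")
}

#' @export
print.triplet <- function(x, ...) {
  cat(sprintf("<triplet> unit %s, pair %s\n", x$unit_id, x$stimulus_pair_id))
  cat(sprintf("  A : n=%2d  mean=%.2f\n", length(x$a_counts), mean(x$a_counts)))
  cat(sprintf("  B : n=%2d  mean=%.2f\n", length(x$b_counts), mean(x$b_counts)))
  cat(sprintf("  AB: n=%2d  mean=%.2f\n", length(x$ab_counts), mean(x$ab_counts)))
  invisible(x)
}

#' Detect microsaccades in an eye-speed trace
#'
#' Flags maximal contiguous runs of stimulus-epoch samples whose eye speed
#' exceeds the fixation-epoch mean by more than `n_sd` fixation-epoch
#' standard deviations (unbiased estimator). The inequality is strict, so
#' with a constant fixation trace (sd = 0) only samples strictly above the
#' mean are flagged, and a sample sitting exactly at the threshold never
#' is. A trial is conventionally excluded when the returned list is
#' nonempty.
#'
#' @param eye_speed numeric vector of sampled eye speed.
#' @param fixation_epoch,stimulus_epoch integer index vectors into
#'   `eye_speed` marking the two epochs.
#' @param n_sd threshold in fixation-epoch standard deviations (default 6).
#' @return a list of integer ranges, each `c(start, end)` in trace indices;
#'   empty if no sample exceeds the threshold.
#' @export
detect_microsaccades <- function(eye_speed, fixation_epoch, stimulus_epoch,
                                 n_sd = 6) {
  if (length(fixation_epoch) == 0)
    stop_input("fixation epoch is empty")
  if (!is.numeric(n_sd) || length(n_sd) != 1 || !is.finite(n_sd) || n_sd <= 0)
    stop_input("`n_sd` must be a single positive number")
  fix <- eye_speed[fixation_epoch]
  if (any(!is.finite(fix)))
    stop_input("non-finite eye speed in fixation epoch")
  s <- if (length(fix) > 1) stats::sd(fix) else 0
  thr <- mean(fix) + n_sd * s
  over <- eye_speed[stimulus_epoch] > thr
  over[is.na(over)] <- FALSE
  if (!any(over)) return(list())
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k)
    c(stimulus_epoch[starts[k]], stimulus_epoch[ends[k]]))
}

#' Read per-trial spike data from a delimited file
#'
#' The expected dialect is one row per trial with columns `unit_id`,
#' `trial_id`, `condition` (one of `A`, `B`, `AB`), `stimulus_a_id`,
#' `stimulus_b_id`, `correct` (logical or 0/1), and either `spike_count`
#' or `spike_times` (semicolon-separated seconds relative to stimulus
#' onset). Missing single-stimulus identifiers are allowed on A-alone and
#' B-alone rows. An optional companion eye-trace file has columns
#' `trial_id`, `speeds` (semicolon-separated samples), `fix_start`,
#' `fix_end`, `stim_start`, `stim_end` (sample indices, 1-based).
#'
#' @param path path to the trial table (CSV, or TSV by extension).
#' @param eye_path optional path to the companion eye-trace table.
#' @return a data.frame of trials; when eye traces are supplied, an
#'   `eye` list-column holds per-trial traces with epoch indices.
#' @export
read_trials <- function(path, eye_path = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("unit_id", "trial_id", "condition", "correct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("trial table lacks columns: ", paste(miss, collapse = ", "))
  if (!("spike_count" %in% names(df)) && !("spike_times" %in% names(df)))
    stop_input("trial table needs `spike_count` or `spike_times`")
  df$correct <- as.logical(df$correct)
  if (!is.null(eye_path)) {
    ey <- utils::read.table(eye_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    traces <- lapply(seq_len(nrow(ey)), function(i) list(
      speed = as.numeric(strsplit(ey$speeds[i], ";", fixed = TRUE)[[1]]),
      fixation = ey$fix_start[i]:ey$fix_end[i],
      stimulus = ey$stim_start[i]:ey$stim_end[i]))
    df$eye <- traces[match(df$trial_id, ey$trial_id)]
  }
  df
}

#' Write a trial table in the dialect `read_trials()` reads
#'
#' @param trials a trial data.frame (as produced by
#'   [as_trials()] or assembled by the caller).
#' @param path output path; comma-separated.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials[setdiff(names(trials), "eye")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

parse_spike_times <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

trial_count <- function(row, window) {
  if (!is.null(row$spike_count) && !is.na(row$spike_count))
    return(as.integer(row$spike_count))
  if (!is.null(row$spike_times) && !is.na(row$spike_times))
    return(count_spikes(parse_spike_times(row$spike_times), window))
  stop_input("trial ", row$trial_id, " has neither spike_count nor spike_times")
}

#' Assemble triplets from a trial table
#'
#' Groups trials of each unit by stimulus pair and assembles one triplet
#' per (unit, pair) that retains at least one trial of each condition
#' after trial-level filters: incorrect trials are dropped, and when an
#' eye trace is attached to a trial, trials containing a detected
#' microsaccade during the stimulus epoch are dropped (trials without eye
#' data pass through). Counts are taken from `spike_count` when present,
#' otherwise computed from `spike_times` over `window`. A-alone (B-alone)
#' rows carrying only their own stimulus id are matched to every pair that
#' uses that stimulus in that role. Count vectors are ordered by
#' `trial_id` so assembly is invariant to row order.
#'
#' @param trials a trial data.frame, see [read_trials()].
#' @param window a [count_window()] used when counts must be computed
#'   from timestamps.
#' @param n_sd microsaccade threshold passed to [detect_microsaccades()].
#' @return a list of [triplet()] objects.
#' @export
build_triplets <- function(trials, window = window_preset("MT"), n_sd = 6) {
  trials <- trials[trials$correct %in% TRUE, , drop = FALSE]
  if (!nrow(trials)) return(list())

  has_eye <- "eye" %in% names(trials)
  keep <- vapply(seq_len(nrow(trials)), function(i) {
    if (!has_eye) return(TRUE)
    tr <- trials$eye[[i]]
    if (is.null(tr) || !is.list(tr)) return(TRUE)
    length(detect_microsaccades(tr$speed, tr$fixation, tr$stimulus, n_sd)) == 0
  }, logical(1))
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) return(list())

  cond <- toupper(trimws(trials$condition))
  bad <- !(cond %in% c("A", "B", "AB"))
  if (any(bad)) {
    warning(sum(bad), " trial(s) with unresolvable condition label skipped")
    trials <- trials[!bad, , drop = FALSE]
    cond <- cond[!bad]
  }
  sa <- if ("stimulus_a_id" %in% names(trials)) as.character(trials$stimulus_a_id)
        else rep(NA_character_, nrow(trials))
  sb <- if ("stimulus_b_id" %in% names(trials)) as.character(trials$stimulus_b_id)
        else rep(NA_character_, nrow(trials))

  counts <- vapply(seq_len(nrow(trials)), function(i)
    trial_count(trials[i, , drop = FALSE], window), integer(1))
  byid <- function(ix) ix[order(trials$trial_id[ix])]

  out <- list()
  for (u in unique(trials$unit_id)) {
    iu <- which(trials$unit_id == u)
    abt <- iu[cond[iu] == "AB"]
    pairs <- unique(data.frame(sa = sa[abt], sb = sb[abt],
                               stringsAsFactors = FALSE))
    if (!nrow(pairs)) { # no stimulus ids at all: single implicit pair
      pairs <- data.frame(sa = NA_character_, sb = NA_character_)
    }
    for (p in seq_len(nrow(pairs))) {
      pa <- pairs$sa[p]; pb <- pairs$sb[p]
      same <- function(x, y) (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
      i_ab <- iu[cond[iu] == "AB" & same(sa[iu], pa) & same(sb[iu], pb)]
      i_a  <- iu[cond[iu] == "A" & (same(sa[iu], pa)) &
                   (is.na(sb[iu]) | same(sb[iu], pb))]
      i_b  <- iu[cond[iu] == "B" & (same(sb[iu], pb)) &
                   (is.na(sa[iu]) | same(sa[iu], pa))]
      if (!length(i_a) || !length(i_b) || !length(i_ab)) next
      out[[length(out) + 1]] <- triplet(
        counts[byid(i_a)], counts[byid(i_b)], counts[byid(i_ab)],
        unit_id = u,
        stimulus_pair_id = if (is.na(pa) && is.na(pb)) NA_character_
                           else paste0(pa, "+", pb))
    }
  }
  out
}
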