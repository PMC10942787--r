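pipeline_default_config <- function() {
  list(
    input = list(type = "synthetic", path = NULL, eye_path = NULL,
                 preset = "regimes-demo", n_per_regime = 5L,
                 n_trials = 15L),
    window = "MT",
    screening = list(min_trials = 5L, max_mean_fano = 3,
                     min_log_ibf_separation = 3, separation_prior_odds = 1),
    model = list(hypothesis_priors = c(0.25, 0.25, 0.25, 0.25),
                 rate_prior_shape = 0.5, rate_prior_rate = 1e-6,
                 outside_cap_multiplier = 2, n_rate_nodes = 31L,
                 n_alpha_nodes = 63L, fluctuation_threshold = 0.67),
    tally_threshold = 0.67,
    seed = 1L,
    output_dir = "spikemux_out",
    figures = FALSE,
    log_level = "info")
}

merge_checked <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_input("unknown config field(s): ",
               paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_checked(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a configuration as a named list or a path to a YAML/JSON
#' document, fills in the documented defaults (equal 25% hypothesis
#' priors, 0.67 thresholds, Fano ceiling 3, log-IBF floor 3, 5-trial
#' minimum, MT window), rejects unknown keys, and validates ranges. The
#' `window` entry may be a preset name (`"MT"`, `"IT"`, `"IT_long"`) or
#' a list with `latency_offset` and `duration` in seconds.
#'
#' @param config named list, or path to a YAML (or JSON) file; `NULL`
#'   yields the full default configuration.
#' @return an object of class `pipeline_config`: the normalized list
#'   with `window`, `screening` and `model` resolved to their
#'   constructor objects.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop_input("`config` must be a list or a file path")
  cfg <- merge_checked(pipeline_default_config(), config)

  if (!(cfg$input$type %in% c("synthetic", "csv")))
    stop_input("input.type must be 'synthetic' or 'csv'")
  if (cfg$input$type == "csv" && is.null(cfg$input$path))
    stop_input("input.path is required for input.type = 'csv'")

  cfg$window <- if (is.character(cfg$window)) window_preset(cfg$window)
    else count_window(cfg$window$latency_offset, cfg$window$duration)
  cfg$screening <- do.call(screening_config, cfg$screening)
  cfg$model <- do.call(model_config, cfg$model)
  if (!(cfg$tally_threshold >= 0 && cfg$tally_threshold <= 1))
    stop_input("tally_threshold must lie in [0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

synthetic_preset_trials <- function(input, seed) {
  regimes <- switch(input$preset,
    "regimes-demo" = c("mixture", "intermediate", "single_A", "single_B",
                       "outside_high", "outside_low"),
    "caveats-demo" = c("mid_trial_switch", "mixture"),
    stop_input("unknown synthetic preset: ", input$preset))
  n <- as.integer(input$n_per_regime)
  nt <- as.integer(input$n_trials)
  specs <- lapply(rep(regimes, each = n), function(r)
    regime_spec(r, n_a = nt, n_b = nt, n_ab = nt))
  pop <- simulate_population(specs, master_seed = seed)
  trials <- as_trials(pop)
  trials$group <- rep(vapply(pop$specs, `[[`, character(1), "regime"),
                      times = vapply(pop$triplets, function(tr)
                        length(tr$a_counts) + length(tr$b_counts) +
                          length(tr$ab_counts), integer(1)))
  trials
}

#' Run the full multiplexing analysis pipeline
#'
#' Ingests (or simulates) trials, assembles triplets, screens them,
#' classifies the included ones, tallies categories (overall and per
#' `group` when the trial table carries a group column), compares
#' mixture prevalence between every pair of groups, and writes CSV
#' reports plus a JSON run manifest to the output directory. The run is
#' deterministic given the configuration.
#'
#' @param config anything [validate_config()] accepts.
#' @param output_dir overrides the configured output directory.
#' @return invisibly, a list with `trials`, `triplets`, `screening`,
#'   `classifications`, `tallies`, `comparisons` and `manifest`.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (identical(cfg$log_level, "info"))
    message("[spikemux] ", sprintf(...))

  if (cfg$input$type == "synthetic") {
    trials <- synthetic_preset_trials(cfg$input, cfg$seed)
    write_trials(trials, file.path(out_dir, "trials.csv"))
  } else {
    trials <- read_trials(cfg$input$path, cfg$input$eye_path)
  }
  log_msg("%d trials read", nrow(trials))

  triplets <- build_triplets(trials, cfg$window)
  log_msg("%d triplets assembled", length(triplets))

  screening <- screen_triplets(triplets, cfg$screening)
  utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  included <- triplets[screening$included]
  log_msg("%d triplets included (%d screened out: %s)",
          length(included), sum(!screening$included),
          paste(names(table(screening$failure_reasons[
            !screening$included])), collapse = ", "))

  classifications <- classify_triplets(included, cfg$model)
  if (is.null(classifications))
    classifications <- classify_triplets(list())  # zero-row frame
  group_of <- NULL
  if (!is.null(classifications) && nrow(classifications) &&
      "group" %in% names(trials)) {
    group_of <- tapply(trials$group, trials$unit_id, function(g) g[[1]])
    classifications$group <-
      as.character(group_of[classifications$unit_id])
  }
  utils::write.csv(classifications,
                   file.path(out_dir, "classifications.csv"),
                   row.names = FALSE)

  tallies <- list(overall = tally_classifications(
    classifications, cfg$tally_threshold, regime = "overall",
    n_screened_out = sum(!screening$included)))
  if (!is.null(classifications$group)) {
    for (g in sort(unique(classifications$group)))
      tallies[[g]] <- tally_classifications(
        classifications[classifications$group == g, , drop = FALSE],
        cfg$tally_threshold, regime = g)
  }
  tally_df <- do.call(rbind, lapply(tallies, function(t) data.frame(
    regime = t$regime, t(t$counts), n_unclassified = t$n_unclassified,
    n_screened_out = t$n_screened_out, stringsAsFactors = FALSE)))
  utils::write.csv(tally_df, file.path(out_dir, "tallies.csv"),
                   row.names = FALSE)

  comparisons <- NULL
  gnames <- setdiff(names(tallies), "overall")
  if (length(gnames) >= 2) {
    pairs <- utils::combn(gnames, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(p) {
      cmp <- tryCatch(compare_mixture_prevalence(tallies[[p[1]]],
                                                 tallies[[p[2]]]),
                      error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      data.frame(regime_1 = p[1], regime_2 = p[2],
                 statistic = cmp$statistic, dof = cmp$dof,
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    }))
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
  }

  if (isTRUE(cfg$figures)) {
    tryCatch({
      grDevices::png(file.path(out_dir, "tallies.png"), width = 600,
                     height = 400)
      plot(tallies$overall)
      grDevices::dev.off()
    }, error = function(e) warning("figure device unavailable: ",
                                   conditionMessage(e)))
  }

  manifest <- list(
    package = "spikemux",
    version = as.character(utils::packageVersion("spikemux")),
    seed = cfg$seed,
    config = config_echo(cfg),
    n_trials = nrow(trials),
    n_triplets = length(triplets),
    n_included = length(included),
    n_classified = sum(tallies$overall$counts),
    n_unclassified = tallies$overall$n_unclassified)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(trials = trials, triplets = triplets,
                 screening = screening,
                 classifications = classifications,
                 tallies = tallies, comparisons = comparisons,
                 manifest = manifest))
}

config_echo <- function(cfg) {
  list(input = cfg$input,
       window = list(latency_offset = cfg$window$latency_offset,
                     duration = cfg$window$duration),
       screening = unclass(cfg$screening),
       model = as.list(unclass(cfg$model)),
       tally_threshold = cfg$tally_threshold,
       seed = cfg$seed, output_dir = cfg$output_dir,
       figures = cfg$figures, log_level = cfg$log_level)
}
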