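#' Behavioral session performance
#'
#' Fraction of correct stimulus trials: hits (lick on C2) plus correct
#' rejections (no lick on B2) over all stimulus trials. Sessions are included
#' in the axonal analysis only when performance exceeds chance (fraction
#' strictly greater than 0.6).
#'
#' @param trials trial table.
#' @return fraction in \[0, 1\].
#' @export
session_performance <- function(trials) {
  stim <- trials$condition %in% c("C2", "B2")
  if (!any(stim)) stop("no stimulus trials; performance undefined", call. = FALSE)
  mean(trials$outcome[stim] %in% c("hit", "correct_rejection"))
}

#' Session inclusion criterion
#'
#' @param performance fraction correct from [session_performance()].
#' @param threshold inclusion threshold (default 0.6, strict inequality).
#' @return logical.
#' @export
session_included <- function(performance, threshold = 0.6) {
  performance > threshold
}

write_table_with_provenance <- function(df, path, seed, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thalaxon %s | seed=%d | n_trials=%d | frame_rate=%g",
                     as.character(utils::packageVersion("thalaxon")),
                     seed, cfg$n_trials, cfg$frame_rate), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full synthetic-session analysis pipeline
#'
#' simulate -> merge -> normalize -> trial z-score -> response statistics ->
#' spatial overlap -> lick-timing correlation, from one master seed. Applies
#' the session-inclusion criterion and, when `out_dir` is given, writes the
#' result tables as CSV with a provenance header line (`# thalaxon <version> |
#' seed=... | ...`).
#'
#' @param cfg a [session_config()].
#' @param beh a [behavior_config()].
#' @param pop_cfg a [population_config()].
#' @param seed master seed.
#' @param out_dir optional output directory for CSV tables.
#' @param merge_threshold segment-correlation merge threshold.
#' @param early_window early analysis window, s.
#' @return a `session_result` list: `config`, `seed`, `performance`,
#'   `included`, `trials`, `truth`, `merged`, `tensors`, `responses` (per
#'   condition/lick group), `wsi`, `overlap`, `timing`, and `paths` when
#'   written.
#' @export
run_pipeline <- function(cfg = session_config(), beh = behavior_config(),
                         pop_cfg = population_config(), seed = 1L,
                         out_dir = NULL, merge_threshold = 0.8,
                         early_window = 0.266) {
  session <- simulate_session(cfg, beh, pop_cfg, seed = seed)
  trials <- session$trials
  perf <- session_performance(trials)

  partition <- correlation_cluster(session$segments, threshold = merge_threshold)
  merged <- merge_segments(session$segments, partition)
  tensors <- lapply(merged, function(ax) {
    trial_zscore(normalize_trace(ax), trials, session$config)
  })
  resp <- lapply(tensors, axon_response, early_window = early_window)
  responses <- do.call(rbind, lapply(resp, `[[`, "by_group"))
  wsi <- do.call(rbind, lapply(resp, `[[`, "wsi"))

  # sensory tuning map from no-lick trials: lick-locked transients are more
  # frequent on rewarded C2 trials and would bias pooled-trial WSI toward C2
  map <- pixel_tuning_map(merged, wsi[wsi$lick_group == "nolick", ])
  overlap <- field_overlap(map)
  timing <- session_timing_correlation(tensors, trials)

  result <- list(config = session$config, behavior = beh, seed = seed,
                 performance = perf, included = session_included(perf),
                 trials = trials, truth = session$truth,
                 partition = partition, merged = merged, tensors = tensors,
                 responses = responses, wsi = wsi, map = map,
                 overlap = overlap, timing = timing)
  class(result) <- "session_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(trials = trials, responses = responses, wsi = wsi,
                   overlap = overlap, timing = timing)
    paths <- vapply(names(tables), function(nm) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_table_with_provenance(tables[[nm]], p, seed, session$config)
      p
    }, character(1))
    result$paths <- paths
  }
  result
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("thalaxon session (seed %d): %d trials, %d merged axons\n",
              x$seed, nrow(x$trials), length(x$merged)))
  cat(sprintf("  performance %.3f (%s)\n", x$performance,
              if (x$included) "included" else "excluded"))
  if (!is.na(x$overlap$overlap_index))
    cat(sprintf("  C2/B2 tuned-pixel overlap index %.3f\n",
                x$overlap$overlap_index))
  nsig <- sum(x$responses$significant[x$responses$lick_group == "all" &
                                        x$responses$condition != "none"])
  cat(sprintf("  %d significant condition responses (pooled trials)\n", nsig))
  invisible(x)
}
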