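#' Single-trial response latency from the cumulative signal
#'
#' Latency of the dominant response component in one trial: the z-scored
#' signal is rectified at zero (the cumulation needs nonnegative mass),
#' summed over a window starting at the response-window onset, and the
#' latency is the time of the first bin whose running sum reaches 50% of the
#' window total. A median-mass latency is insensitive to an early
#' stimulus-locked component when a later lick-locked component dominates,
#' which is what makes it usable for lick-timing correlation.
#'
#' @param trial_z z-scored signal for one trial, bin 0 at the response-window
#'   onset.
#' @param bin_period bin duration, s.
#' @param window cumulation window length, s (default 3).
#' @param rectify floor negative z at 0 before cumulation (default TRUE).
#' @return latency in s from window onset, or `NA` when the window total is
#'   not positive (trial excluded).
#' @export
cumulative_latency <- function(trial_z, bin_period, window = 3,
                               rectify = TRUE) {
  n_bins <- as.integer(round(window / bin_period))
  if (length(trial_z) < n_bins)
    stop("trial shorter than the cumulation window", call. = FALSE)
  x <- trial_z[seq_len(n_bins)]
  if (rectify) x <- pmax(x, 0)
  total <- sum(x)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  idx <- which(cumsum(x) >= total / 2)[1]
  (idx - 1) * bin_period
}

#' Correlation between response latency and lick reaction time
#'
#' Pearson correlation over trials between the cumulative-signal latency and
#' the first-lick reaction time, with its two-sided p-value; an axon is
#' flagged when p < 0.05. Computed on lick trials of the non-rewarded (B2)
#' condition, where the licking pattern is comparable across trials.
#'
#' @param latencies per-trial response latencies, s.
#' @param reaction_times per-trial first-lick reaction times, s.
#' @return list: `n`, `pearson_r`, `p_value`, `flagged`; all `NA`/`FALSE` with
#'   a reason when fewer than 3 finite pairs remain or either vector is
#'   constant.
#' @export
timing_correlation <- function(latencies, reaction_times) {
  ok <- is.finite(latencies) & is.finite(reaction_times)
  x <- latencies[ok]; y <- reaction_times[ok]
  bad <- function(reason) list(n = length(x), pearson_r = NA_real_,
                               p_value = NA_real_, flagged = FALSE,
                               reason = reason)
  if (length(x) < 3) return(bad("fewer than 3 paired trials"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(bad("zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(n = length(x), pearson_r = unname(ct$estimate), p_value = ct$p.value,
       flagged = ct$p.value < 0.05, reason = NA_character_)
}

#' Event-triggered average of a normalized trace
#'
#' Mean and s.e.m. of the noise-normalized signal aligned to a set of event
#' times (e.g. isolated spontaneous licks, or lick-bout offsets). Events whose
#' window does not fit inside the session are dropped.
#'
#' @param norm a `normalized_trace`.
#' @param event_times_s event times in seconds of trace time (frame / rate).
#' @param frame_rate acquisition rate, Hz.
#' @param window `c(-t_pre, t_post)` in seconds around each event.
#' @return list: `time`, `mean`, `sem`, `n_events`; `n_events = 0` with empty
#'   vectors when no usable event remains.
#' @export
event_triggered_average <- function(norm, event_times_s, frame_rate,
                                    window = c(-1, 3)) {
  stopifnot(inherits(norm, "normalized_trace"))
  n <- length(norm$normalized)
  offs <- seq(round(window[1] * frame_rate), round(window[2] * frame_rate))
  frames <- round(event_times_s * frame_rate)
  frames <- frames[frames + offs[1] >= 0 & frames + offs[length(offs)] < n]
  if (length(frames) == 0)
    return(list(time = numeric(0), mean = numeric(0), sem = numeric(0),
                n_events = 0L))
  m <- t(vapply(frames, function(f) norm$normalized[f + offs + 1L],
                numeric(length(offs))))
  list(time = offs / frame_rate,
       mean = colMeans(m),
       sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
       n_events = length(frames))
}

#' Lick-timing correlation for every axon of a session
#'
#' Applies [cumulative_latency()] to each B2 lick trial of each axon's trial
#' tensor and correlates the latencies with the trials' reaction times.
#'
#' @param tensors list of `trial_tensor` objects (stimulus-aligned).
#' @param trials the session trial table.
#' @param window cumulation window, s.
#' @param rectify see [cumulative_latency()].
#' @return data.frame per axon: `axon_id`, `n_trials`, `pearson_r`,
#'   `p_value`, `flagged`.
#' @export
session_timing_correlation <- function(tensors, trials, window = 3,
                                       rectify = TRUE) {
  rows <- lapply(tensors, function(tensor) {
    g <- tensor$groups[["B2.lick"]]
    if (is.null(g))
      return(data.frame(axon_id = tensor$axon_id, n_trials = 0L,
                        pearson_r = NA_real_, p_value = NA_real_,
                        flagged = FALSE))
    post <- which(tensor$time >= 0)
    lat <- apply(g$z[, post, drop = FALSE], 1, cumulative_latency,
                 bin_period = tensor$bin_period, window = window,
                 rectify = rectify)
    tc <- timing_correlation(lat, trials$reaction_time_s[g$trials])
    data.frame(axon_id = tensor$axon_id, n_trials = tc$n,
               pearson_r = tc$pearson_r, p_value = tc$p_value,
               flagged = tc$flagged)
  })
  do.call(rbind, rows)
}
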