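#' Per-bin one-sided z-tests over trials
#'
#' For each time bin the mean z over trials is tested against the
#' standard-normal null: the values are noise-normalized and z-scored against
#' the pre-window, so under the null each bin is unit-variance and the test
#' statistic is `mean * sqrt(n)` with an upper-tail normal p-value.
#' `neg_log10_p` is computed on the log scale so it does not saturate when p
#' underflows double precision.
#'
#' @param tensor_slice trials x bins matrix of z-scored signal.
#' @return data.frame per bin: `bin` (0-based), `n`, `mean_z`, `statistic`,
#'   `p`, `neg_log10_p`.
#' @export
binwise_ztest <- function(tensor_slice) {
  m <- as.matrix(tensor_slice)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 trials per bin", call. = FALSE)
  mean_z <- colMeans(m)
  stat <- mean_z * sqrt(n)
  p <- stats::pnorm(stat, lower.tail = FALSE)
  nlp <- -stats::pnorm(stat, lower.tail = FALSE, log.p = TRUE) / log(10)
  data.frame(bin = seq_along(mean_z) - 1L, n = n, mean_z = mean_z,
             statistic = stat, p = p, neg_log10_p = nlp)
}

#' Consecutive-bin significance call
#'
#' A response is significant when `-log10(p)` exceeds the threshold in at
#' least `min_consecutive` consecutive bins. The consecutive-bin requirement
#' exploits the slow GCaMP6s dynamics to reject spurious single-bin
#' significance.
#'
#' @param neg_log10_p vector of `-log10(p)` per bin, restricted to the
#'   response window.
#' @param threshold significance threshold on `-log10(p)` (default 10).
#' @param min_consecutive minimum run length (default 3).
#' @return logical.
#' @export
detect_significance <- function(neg_log10_p, threshold = 10,
                                min_consecutive = 3) {
  if (length(neg_log10_p) < min_consecutive) return(FALSE)
  r <- rle(neg_log10_p > threshold)
  any(r$values & r$lengths >= min_consecutive)
}

#' Response latency from the binwise p-value trace
#'
#' For significant responses, the latency is the time of the first bin
#' (0-based, relative to stimulus onset) where `-log10(p)` exceeds the latency
#' threshold (default 5, more permissive than the significance threshold so
#' the response onset is not clipped).
#'
#' @param neg_log10_p vector of `-log10(p)` per post-onset bin.
#' @param bin_period bin duration, s.
#' @param latency_threshold threshold on `-log10(p)` (default 5).
#' @return latency in seconds.
#' @export
response_latency <- function(neg_log10_p, bin_period,
                             latency_threshold = 5) {
  idx <- which(neg_log10_p > latency_threshold)
  if (length(idx) == 0)
    stop("no bin exceeds the latency threshold despite a significance call",
         call. = FALSE)
  (idx[1] - 1) * bin_period
}

#' Windowed response amplitude
#'
#' Mean z over trials and bins in a half-open time window `[t0, t1)` relative
#' to the alignment point of a tensor group.
#'
#' @param group a `trial_tensor` group (list with `z`).
#' @param time time axis of the tensor (s; from `trial_tensor$time`).
#' @param window numeric `c(t0, t1)` in seconds.
#' @return mean z (scalar).
#' @export
response_amplitude <- function(group, time, window = c(0, 2)) {
  cols <- which(time >= window[1] & time < window[2])
  if (length(cols) == 0) stop("window outside the tensor", call. = FALSE)
  mean(group$z[, cols, drop = FALSE])
}

#' Whisker selectivity index
#'
#' `(C2 - B2) / (C2 + B2)` of the windowed response amplitudes. Negative
#' amplitudes are floored at zero first so the index stays in \[-1, 1\]; when
#' both floored amplitudes are zero the index is undefined (`NA`) and the axon
#' is excluded from selectivity summaries. `|WSI| >= 0.75` defines a "tuned"
#' axon.
#'
#' @param amp_c2,amp_b2 windowed mean-z amplitudes.
#' @return WSI in \[-1, 1\], or `NA`.
#' @export
whisker_selectivity_index <- function(amp_c2, amp_b2) {
  a <- pmax(amp_c2, 0)
  b <- pmax(amp_b2, 0)
  ifelse(a + b > 0, (a - b) / (a + b), NA_real_)
}

#' Tuned / untuned classification
#'
#' @param wsi whisker selectivity index.
#' @param threshold tuning threshold on `|WSI|` (default 0.75).
#' @return logical (`NA` where `wsi` is undefined).
#' @export
is_tuned <- function(wsi, threshold = 0.75) abs(wsi) >= threshold

#' Per-axon response statistics
#'
#' Runs the binwise z-test over the response window for each condition x lick
#' group of a trial tensor and assembles significance, latency, full-window
#' and early-window amplitudes, plus per-lick-group whisker selectivity
#' indices.
#'
#' @param tensor a `trial_tensor` from [trial_zscore()].
#' @param response_window response-window duration after stimulus onset, s.
#' @param early_window early analysis window, s (default 0.266, the last full
#'   30 Hz frame before the mean reaction time).
#' @param sig_threshold,min_consecutive,latency_threshold see
#'   [detect_significance()] and [response_latency()].
#' @param min_trials minimum trials per group for testing.
#' @return list with `by_group` (data.frame: axon_id, condition, lick_group,
#'   n_trials, significant, latency_s, amp_full, amp_early) and `wsi`
#'   (data.frame: axon_id, lick_group, amp_c2, amp_b2, wsi, tuned).
#' @export
axon_response <- function(tensor, response_window = 2, early_window = 0.266,
                          sig_threshold = 10, min_consecutive = 3,
                          latency_threshold = 5, min_trials = 2) {
  stopifnot(inherits(tensor, "trial_tensor"))
  time <- tensor$time
  rows <- list()
  for (gname in names(tensor$groups)) {
    parts <- strsplit(gname, ".", fixed = TRUE)[[1]]
    g <- tensor$groups[[gname]]
    if (g$n_trials < min_trials) next
    resp_cols <- which(time >= 0 & time < response_window)
    bt <- binwise_ztest(g$z[, resp_cols, drop = FALSE])
    sig <- detect_significance(bt$neg_log10_p, sig_threshold, min_consecutive)
    lat <- if (sig) response_latency(bt$neg_log10_p, tensor$bin_period,
                                     latency_threshold) else NA_real_
    rows[[gname]] <- data.frame(
      axon_id = tensor$axon_id, condition = parts[1], lick_group = parts[2],
      n_trials = g$n_trials, significant = sig, latency_s = lat,
      amp_full = response_amplitude(g, time, c(0, response_window)),
      amp_early = response_amplitude(g, time, c(0, early_window)),
      stringsAsFactors = FALSE)
  }
  by_group <- do.call(rbind, rows)
  rownames(by_group) <- NULL
  wsi_rows <- list()
  for (lg in unique(by_group$lick_group)) {
    a <- by_group[by_group$condition == "C2" & by_group$lick_group == lg, ]
    b <- by_group[by_group$condition == "B2" & by_group$lick_group == lg, ]
    if (nrow(a) == 1 && nrow(b) == 1) {
      w <- whisker_selectivity_index(a$amp_full, b$amp_full)
      wsi_rows[[lg]] <- data.frame(axon_id = tensor$axon_id, lick_group = lg,
                                   amp_c2 = a$amp_full, amp_b2 = b$amp_full,
                                   wsi = w, tuned = is_tuned(w),
                                   stringsAsFactors = FALSE)
    }
  }
  list(by_group = by_group,
       wsi = if (length(wsi_rows)) do.call(rbind, wsi_rows) else NULL)
}

#' Early-window lick vs no-lick comparison
#'
#' Compares per-axon early-window response amplitudes between lick and
#' no-lick trials with a paired two-sided Wilcoxon signed-rank test. An early
#' window shorter than the mean reaction time isolates the pre-decision part
#' of the response; the default 0.266 s is robust to slightly larger (0.4 s)
#' or smaller (0.2 s) choices. When all paired differences are zero the
#' p-value is 1 by convention. Amplitudes can be normalized to the no-lick
#' condition for display.
#'
#' @param amp_lick,amp_nolick per-axon early-window amplitudes (equal length,
#'   paired by axon).
#' @param normalize divide both by the mean no-lick amplitude.
#' @return list: `table` (per-axon amplitudes and differences), `p_value`,
#'   `n`, `mean_lick`, `mean_nolick`.
#' @export
early_window_comparison <- function(amp_lick, amp_nolick, normalize = FALSE) {
  ok <- is.finite(amp_lick) & is.finite(amp_nolick)
  amp_lick <- amp_lick[ok]; amp_nolick <- amp_nolick[ok]
  if (length(amp_lick) == 0) stop("no paired axons", call. = FALSE)
  if (normalize) {
    ref <- mean(amp_nolick)
    amp_lick <- amp_lick / ref; amp_nolick <- amp_nolick / ref
  }
  d <- amp_lick - amp_nolick
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(amp_lick, amp_nolick,
                                        paired = TRUE)$p.value)
  list(table = data.frame(amp_lick = amp_lick, amp_nolick = amp_nolick,
                          diff = d),
       p_value = p, n = length(d),
       mean_lick = mean(amp_lick), mean_nolick = mean(amp_nolick))
}
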