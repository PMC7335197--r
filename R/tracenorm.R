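#' Half-sample mode
#'
#' Robust mode estimator (Robertson & Cryer / Bickel): repeatedly restrict to
#' the half of the sorted sample with the smallest range. Parameter-free, and
#' insensitive to sparse positive transients riding on the baseline, which is
#' what makes it suitable for GCaMP baseline estimation.
#'
#' @param x numeric vector.
#' @return scalar mode estimate.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite values", call. = FALSE)
  while (n > 3) {
    m <- ceiling(n / 2)
    ranges <- x[m:n] - x[1:(n - m + 1)]
    i <- which.min(ranges)
    x <- x[i:(i + m - 1)]
    n <- m
  }
  if (n == 3) {
    d1 <- x[2] - x[1]; d2 <- x[3] - x[2]
    if (d1 < d2) mean(x[1:2]) else if (d2 < d1) mean(x[2:3]) else x[2]
  } else {
    mean(x)
  }
}

#' Estimate the slow fluorescence baseline
#'
#' The signal mode is estimated piecewise in segments of `segment_length`
#' frames (half-sample mode per segment), and the (segment center, mode)
#' points are fitted by a least-squares polynomial of order `poly_order`,
#' evaluated at every frame. This filters out spurious high-frequency
#' components while tracking slow drift; because the mode ignores sparse
#' positive transients, calcium events do not bias the baseline.
#'
#' Traces shorter than `segment_length` are treated as a single segment; when
#' there are fewer mode points than `poly_order + 1` the order is reduced with
#' a warning.
#'
#' @param trace numeric fluorescence trace.
#' @param segment_length frames per mode segment (default 3000).
#' @param poly_order polynomial order (default 5).
#' @return numeric baseline, same length as `trace`.
#' @export
estimate_baseline <- function(trace, segment_length = 3000, poly_order = 5) {
  n <- length(trace)
  if (n < 2) stop("trace too short", call. = FALSE)
  n_seg <- max(1L, n %/% as.integer(segment_length))
  bounds <- round(seq(0, n, length.out = n_seg + 1))
  centers <- numeric(n_seg)
  modes <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    centers[i] <- mean(idx)
    modes[i] <- half_sample_mode(trace[idx])
  }
  order_used <- poly_order
  if (n_seg < poly_order + 1) {
    order_used <- n_seg - 1L
    warning(sprintf("only %d mode points; polynomial order reduced to %d",
                    n_seg, order_used))
  }
  if (order_used == 0) return(rep(modes[1], n))
  # Abscissae scaled to [0, 1] for conditioning; extrapolated beyond the
  # first/last segment centers.
  xc <- (centers - 1) / (n - 1)
  fit <- stats::lm.fit(outer(xc, 0:order_used, `^`), modes)
  xall <- (seq_len(n) - 1) / (n - 1)
  as.vector(outer(xall, 0:order_used, `^`) %*% fit$coefficients)
}

#' Estimate the noise SD from negative fluctuations
#'
#' GCaMP fluctuations above baseline mix noise with calcium events, but
#' fluctuations below it are noise alone. Assuming a symmetric (Gaussian)
#' noise model, the noise SD is the SD of the mirrored negative residuals
#' \{x, -x : x < 0\}, i.e. the root mean square of the negative residuals.
#'
#' @param residual trace minus baseline.
#' @return noise SD (positive scalar).
#' @export
estimate_noise_sd <- function(residual) {
  neg <- residual[residual < 0]
  if (length(neg) == 0)
    stop("no negative residuals; degenerate baseline", call. = FALSE)
  if (length(neg) < 100)
    warning("fewer than 100 negative residuals; noise estimate unstable")
  sqrt(mean(neg^2))
}

#' Normalize a merged axon trace to noise units
#'
#' Subtracts the piecewise-mode polynomial baseline and divides by the noise
#' SD estimated from negative fluctuations.
#'
#' @param merged a merged axon (list with `axon_id`, `merged_trace`) from
#'   [merge_segments()], or a bare numeric trace.
#' @param segment_length,poly_order passed to [estimate_baseline()].
#' @return a `normalized_trace` list: `axon_id`, `baseline_curve`, `noise_sd`,
#'   `normalized`.
#' @export
normalize_trace <- function(merged, segment_length = 3000, poly_order = 5) {
  if (is.numeric(merged)) merged <- list(axon_id = NA, merged_trace = merged)
  trace <- merged$merged_trace
  baseline <- estimate_baseline(trace, segment_length, poly_order)
  noise_sd <- estimate_noise_sd(trace - baseline)
  structure(list(axon_id = merged$axon_id, baseline_curve = baseline,
                 noise_sd = noise_sd,
                 normalized = (trace - baseline) / noise_sd),
            class = "normalized_trace")
}

#' Trial-aligned z-score tensor
#'
#' Cuts the noise-normalized trace into trial windows aligned to stimulus
#' onset (or to the first lick), groups trials by condition x lick, and
#' z-scores each group against its pooled pre-window distribution: signals in
#' the 0.5 s before the response window are collected across the group's
#' trials, their mean is subtracted and the result divided by their SD.
#'
#' Groups are named `<condition>.<lick>` with lick one of `lick`, `nolick`,
#' `all`. A group whose pre-window SD is zero is marked invalid (dropped with
#' a warning).
#'
#' @param norm a `normalized_trace` from [normalize_trace()].
#' @param trials trial table from [generate_trial_schedule()].
#' @param cfg the [session_config()].
#' @param pre_window pre-response quiet window used for the z-score, s.
#' @param align `"stimulus"` (default) or `"first_lick"`; lick alignment uses
#'   lick trials only and drops trials whose window exceeds the trial.
#' @return a `trial_tensor`: list with `axon_id`, `bin_period`, `n_pre`,
#'   `time` (s relative to the alignment point, bin 0 at alignment), and
#'   `groups`, a named list of lists (`z` trials x bins matrix, `trials`,
#'   `pre_mean`, `pre_sd`, `n_trials`).
#' @export
trial_zscore <- function(norm, trials, cfg, pre_window = 0.5,
                         align = c("stimulus", "first_lick")) {
  align <- match.arg(align)
  stopifnot(inherits(norm, "normalized_trace"), inherits(cfg, "session_config"))
  fr <- cfg$frame_rate
  fpt <- cfg$frames_per_trial
  n_pre <- as.integer(round(pre_window * fr))
  if (pre_window > cfg$quiet_window)
    stop("pre-window must fit inside the quiet window", call. = FALSE)

  align_frame <- trials$stim_onset_frame
  use <- rep(TRUE, nrow(trials))
  if (align == "first_lick") {
    use <- trials$lick & !is.na(trials$reaction_time_s)
    align_frame <- trials$stim_onset_frame +
      round(trials$reaction_time_s * fr)
  }
  trial_start <- (trials$trial - 1L) * fpt
  n_post <- fpt - cfg$stim_onset_within_trial
  # Window must fit inside its trial.
  use <- use & (align_frame - n_pre >= trial_start) &
    (align_frame + n_post <= trial_start + fpt)

  offsets <- seq(-n_pre, n_post - 1L)
  cut_rows <- function(idx) {
    t(vapply(idx, function(k) norm$normalized[align_frame[k] + offsets + 1L],
             numeric(length(offsets))))
  }

  groups <- list()
  for (cond in c("C2", "B2", "none")) {
    for (lg in c("lick", "nolick", "all")) {
      sel <- which(use & trials$condition == cond &
                     (lg == "all" | (lg == "lick") == trials$lick))
      if (length(sel) == 0) next
      m <- cut_rows(sel)
      pre <- m[, seq_len(n_pre), drop = FALSE]
      mu <- mean(pre); sdv <- stats::sd(as.vector(pre))
      if (!is.finite(sdv) || sdv == 0) {
        warning(sprintf("group %s.%s has zero pre-window SD; marked invalid",
                        cond, lg))
        next
      }
      groups[[paste(cond, lg, sep = ".")]] <-
        list(z = (m - mu) / sdv, trials = sel, pre_mean = mu, pre_sd = sdv,
             n_trials = length(sel))
    }
  }
  structure(list(axon_id = norm$axon_id, bin_period = 1 / fr, n_pre = n_pre,
                 time = offsets / fr, groups = groups, align = align),
            class = "trial_tensor")
}
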