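#' Session acquisition and task configuration
#'
#' Describes the trial-based two-photon acquisition scheme and the two-whisker
#' discrimination task: 9 s trials acquired at 30 Hz, a 2 s quiet window
#' followed by a 2 s response window, whisker stimuli of 5 contiguous 40 ms
#' sine pulses, a minimum 4.5 s gap between trials (hence a minimum
#' inter-stimulus interval of 13.5 s), and an 80/20 stimulus/no-stimulus trial
#' mix split evenly between the C2 and B2 whiskers.
#'
#' @param n_trials number of trials in the session.
#' @param frame_rate acquisition rate, Hz.
#' @param trial_duration trial (acquisition sequence) duration, s.
#' @param quiet_window pre-stimulus quiet period, s; the stimulus is delivered
#'   at its end.
#' @param response_window lick-response window after stimulus onset, s.
#' @param stim_duration total whisker stimulus duration, s.
#' @param n_pulses number of sine pulses per stimulus.
#' @param pulse_duration duration of one sine pulse, s.
#' @param min_intertrial_gap minimum gap between the end of one trial and the
#'   start of the next, s.
#' @param stim_fraction fraction of trials carrying a whisker stimulus.
#' @param c2_fraction_of_stim fraction of stimulus trials assigned to C2.
#' @param reward_volume water reward per hit, microliters (bookkeeping only).
#' @param timeout timeout after a false alarm, s (bookkeeping only).
#' @param seed integer seed controlling the trial schedule.
#' @return a `session_config` list.
#' @export
session_config <- function(n_trials = 200,
                           frame_rate = 30,
                           trial_duration = 9,
                           quiet_window = 2,
                           response_window = 2,
                           stim_duration = 0.2,
                           n_pulses = 5,
                           pulse_duration = 0.04,
                           min_intertrial_gap = 4.5,
                           stim_fraction = 0.8,
                           c2_fraction_of_stim = 0.5,
                           reward_volume = 8,
                           timeout = 10,
                           seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (trial_duration <= quiet_window + response_window)
    stop("trial_duration must exceed quiet_window + response_window", call. = FALSE)
  if (abs(n_pulses * pulse_duration - stim_duration) > 1e-9)
    stop("n_pulses * pulse_duration must equal stim_duration", call. = FALSE)
  if (stim_fraction < 0 || stim_fraction > 1)
    stop("stim_fraction must lie in [0, 1]", call. = FALSE)
  if (c2_fraction_of_stim < 0 || c2_fraction_of_stim > 1)
    stop("c2_fraction_of_stim must lie in [0, 1]", call. = FALSE)
  if (frame_rate <= 0 || min_intertrial_gap < 0)
    stop("frame_rate must be positive and min_intertrial_gap nonnegative", call. = FALSE)
  cfg <- list(
    n_trials = as.integer(n_trials), frame_rate = frame_rate,
    trial_duration = trial_duration, quiet_window = quiet_window,
    response_window = response_window, stim_duration = stim_duration,
    n_pulses = as.integer(n_pulses), pulse_duration = pulse_duration,
    min_intertrial_gap = min_intertrial_gap, stim_fraction = stim_fraction,
    c2_fraction_of_stim = c2_fraction_of_stim, reward_volume = reward_volume,
    timeout = timeout, seed = as.integer(seed),
    frames_per_trial = as.integer(round(trial_duration * frame_rate)),
    stim_onset_within_trial = as.integer(round(quiet_window * frame_rate))
  )
  class(cfg) <- "session_config"
  cfg
}

#' Lick-behavior configuration
#'
#' Lick probabilities per stimulus condition and the first-lick reaction-time
#' distribution, a normal with mean 0.29 s and SD 0.18 s truncated to
#' (0, response_window]. A trained animal licks mostly for the rewarded C2
#' whisker, at an intermediate rate for B2, and rarely without a stimulus.
#' Pre-trial licking delays the next trial start beyond the minimum gap; its
#' probability and the delay spread are exposed because they shape the
#' inter-trial timing jitter, though real lick-bout structure is richer.
#'
#' @param p_lick named lick probabilities for conditions C2, B2, none.
#' @param rt_mean,rt_sd mean and SD of the reaction-time normal, s.
#' @param rt_min lower truncation bound of the reaction-time distribution, s
#'   (default 0; the upper bound is the response window).
#' @param p_pretrial_delay probability that pre-trial licking delays a trial
#'   start beyond the minimum inter-trial gap.
#' @param pretrial_delay_max maximum extra delay, s (uniform).
#' @return a `behavior_config` list.
#' @export
behavior_config <- function(p_lick = c(C2 = 0.85, B2 = 0.35, none = 0.10),
                            rt_mean = 0.29, rt_sd = 0.18, rt_min = 0,
                            p_pretrial_delay = 0.3, pretrial_delay_max = 3) {
  if (any(p_lick < 0 | p_lick > 1)) stop("lick probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(c("C2", "B2", "none") %in% names(p_lick)))
    stop("p_lick must name conditions C2, B2 and none", call. = FALSE)
  if (rt_mean <= 0 || rt_sd <= 0) stop("rt_mean and rt_sd must be positive", call. = FALSE)
  if (rt_min < 0) stop("rt_min must be nonnegative", call. = FALSE)
  structure(list(p_lick = p_lick, rt_mean = rt_mean, rt_sd = rt_sd,
                 rt_min = rt_min,
                 p_pretrial_delay = p_pretrial_delay,
                 pretrial_delay_max = pretrial_delay_max),
            class = "behavior_config")
}

# Inverse-CDF draw from normal(mean, sd) truncated to (lo, hi].
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a trial schedule with lick behavior
#'
#' Draws per-trial stimulus conditions (C2 / B2 / none in the configured
#' proportions), lick flags per condition, truncated-normal reaction times for
#' lick trials, and wall-clock trial onsets respecting the minimum inter-trial
#' gap. Trial outcomes follow the task contingencies: lick on C2 = hit
#' (rewarded), lick on B2 = false alarm (timeout), no lick on B2 = correct
#' rejection, no lick on C2 = miss.
#'
#' `stim_onset_frame` is the 0-based index of stimulus onset in the
#' trial-concatenated trace (no inter-trial frames are recorded);
#' `onset_time_s` is the wall-clock onset time including inter-trial gaps.
#'
#' @param cfg a [session_config()].
#' @param beh a [behavior_config()].
#' @return a data.frame with one row per trial: `trial`, `condition`,
#'   `stim_onset_frame`, `onset_time_s`, `lick`, `reaction_time_s` (NA when
#'   no lick), `outcome`.
#' @export
generate_trial_schedule <- function(cfg, beh = behavior_config()) {
  stopifnot(inherits(cfg, "session_config"), inherits(beh, "behavior_config"))
  set.seed(cfg$seed)
  n <- cfg$n_trials
  p <- c(C2 = cfg$stim_fraction * cfg$c2_fraction_of_stim,
         B2 = cfg$stim_fraction * (1 - cfg$c2_fraction_of_stim),
         none = 1 - cfg$stim_fraction)
  condition <- sample(names(p), n, replace = TRUE, prob = p)
  lick <- stats::runif(n) < beh$p_lick[condition]
  rt <- rep(NA_real_, n)
  rt[lick] <- rtruncnorm_inv(sum(lick), beh$rt_mean, beh$rt_sd,
                             beh$rt_min, cfg$response_window)

  # Trial starts: the controller triggers the next acquisition exactly
  # min_intertrial_gap after trial end unless pre-trial licking restarts the
  # wait, adding a uniform delay.
  delayed <- stats::runif(n) < beh$p_pretrial_delay
  extra <- ifelse(delayed, stats::runif(n, 0, beh$pretrial_delay_max), 0)
  gaps <- cfg$min_intertrial_gap + extra
  t_start <- cumsum(c(0, cfg$trial_duration + gaps[-n]))

  outcome <- ifelse(condition == "C2", ifelse(lick, "hit", "miss"),
             ifelse(condition == "B2", ifelse(lick, "false_alarm", "correct_rejection"),
                    ifelse(lick, "no_stim_lick", "no_stim_quiet")))
  data.frame(
    trial = seq_len(n),
    condition = condition,
    stim_onset_frame = (seq_len(n) - 1L) * cfg$frames_per_trial +
      cfg$stim_onset_within_trial,
    onset_time_s = t_start + cfg$quiet_window,
    lick = lick,
    reaction_time_s = rt,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
}

#' Whisker stimulus waveform
#'
#' The piezo displacement command: `n_pulses` contiguous single-period sine
#' pulses of `pulse_duration` each, so the default gives 5 x 40 ms = 200 ms of
#' nonzero support. Sampled at time-bin midpoints so the measured support
#' (`sum(displacement != 0) / sample_rate`) equals the commanded duration
#' exactly and each pulse integrates to zero by symmetry.
#'
#' @param cfg a [session_config()].
#' @param sample_rate waveform sampling rate, Hz.
#' @param pad zero padding before and after the stimulus, s.
#' @return data.frame with `time` (s, 0 = stimulus onset) and `displacement`
#'   (unit amplitude).
#' @export
synthesize_stimulus_waveform <- function(cfg, sample_rate = 1000, pad = 0.05) {
  stopifnot(inherits(cfg, "session_config"), cfg$n_pulses >= 1)
  total <- cfg$stim_duration + 2 * pad
  nsamp <- round(total * sample_rate)
  time <- (seq_len(nsamp) - 0.5) / sample_rate - pad
  in_stim <- time >= 0 & time < cfg$stim_duration
  displacement <- numeric(nsamp)
  displacement[in_stim] <- sin(2 * pi * (time[in_stim] %% cfg$pulse_duration) /
                                 cfg$pulse_duration)
  data.frame(time = time, displacement = displacement)
}

#' GCaMP6s impulse-response kernel
#'
#' Double-exponential fluorescence kernel `(1 - exp(-t/tau_rise)) *
#' exp(-t/tau_decay)`, peak-normalized and sampled at the acquisition frame
#' rate. Default time constants (rise 0.18 s, decay 1.8 s) follow published
#' GCaMP6s kinetics.
#'
#' @param frame_rate sampling rate, Hz.
#' @param tau_rise,tau_decay rise and decay time constants, s.
#' @param duration kernel support, s.
#' @return numeric vector of kernel samples starting at t = 0.
#' @export
gcamp_kernel <- function(frame_rate = 30, tau_rise = 0.18, tau_decay = 1.8,
                         duration = 8) {
  t <- seq(0, duration, by = 1 / frame_rate)
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  k / max(k)
}

# Default per-class generative parameters for the three axon classes.
# VPM-like (lemniscal first-order): sharply whisker-tuned, short latency,
# strong lick-locked transients, no lick gain modulation. POm-FO (paralemniscal
# first-order): bimodally tuned, slower, evoked response enhanced in lick
# trials. POm-HO (higher-order, cortex-recipient): weakly tuned, slowest,
# likewise lick-enhanced.
class_param_defaults <- function() {
  list(
    VPM_like = list(wsi_abs = c(0.80, 1.00), latency = c(0.04, 0.07),
                    amplitude = c(6, 10), lick_transient_gain = c(4, 6),
                    lick_gain_modulation = c(1, 1), bimodal = TRUE,
                    clustered = TRUE),
    POmFO_like = list(wsi_abs = c(0.60, 0.90), latency = c(0.12, 0.18),
                      amplitude = c(5, 8), lick_transient_gain = c(0, 0),
                      lick_gain_modulation = c(1.4, 1.7), bimodal = TRUE,
                      clustered = FALSE),
    POmHO_like = list(wsi_abs = c(0.00, 0.30), latency = c(0.15, 0.25),
                      amplitude = c(4, 7), lick_transient_gain = c(0, 0),
                      lick_gain_modulation = c(1.4, 1.7), bimodal = FALSE,
                      clustered = FALSE)
  )
}

#' Population configuration for the synthetic axon generator
#'
#' @param n_axons number of axons.
#' @param class_proportions named proportions over `VPM_like`, `POmFO_like`,
#'   `POmHO_like`; must sum to 1.
#' @param field_size imaging field size in pixels (rows, cols).
#' @param n_segments_range inclusive range of ROI segments per axon.
#' @param pixels_per_segment inclusive range of pixels per segment.
#' @param segment_correlation within-axon correlation between segment traces,
#'   set through the shared/independent noise variance split; the default 0.9
#'   exceeds the 0.8 merge threshold.
#' @param amplitude_cv trial-to-trial coefficient of variation of evoked event
#'   amplitudes (multiplicative gamma jitter, mean 1). Calcium responses vary
#'   substantially across trials; the jitter is independent across axons,
#'   which keeps distinct axons with similar tuning from correlating above the
#'   merge threshold.
#' @param noise_sd_range per-segment noise SD range, fluorescence units.
#' @param drift_amplitude slow-drift amplitude over the session, fluorescence
#'   units (3rd-order polynomial in normalized time).
#' @param neuropil_coefficient_range per-segment neuropil coefficient range.
#' @param class_params per-class generative parameters; see
#'   `thalaxon:::class_param_defaults`.
#' @return a `population_config` list.
#' @export
population_config <- function(n_axons = 50,
                              class_proportions = c(VPM_like = 1/3,
                                                    POmFO_like = 1/3,
                                                    POmHO_like = 1/3),
                              field_size = c(512, 512),
                              n_segments_range = c(1, 3),
                              pixels_per_segment = c(8, 25),
                              segment_correlation = 0.9,
                              amplitude_cv = 0.7,
                              noise_sd_range = c(0.8, 1.2),
                              drift_amplitude = 3,
                              neuropil_coefficient_range = c(0.5, 0.8),
                              class_params = class_param_defaults()) {
  if (n_axons < 1) stop("population must contain at least one axon", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (segment_correlation <= 0 || segment_correlation >= 1)
    stop("segment_correlation must lie in (0, 1)", call. = FALSE)
  structure(list(n_axons = as.integer(n_axons),
                 class_proportions = class_proportions,
                 field_size = field_size,
                 n_segments_range = n_segments_range,
                 pixels_per_segment = pixels_per_segment,
                 segment_correlation = segment_correlation,
                 amplitude_cv = amplitude_cv,
                 noise_sd_range = noise_sd_range,
                 drift_amplitude = drift_amplitude,
                 neuropil_coefficient_range = neuropil_coefficient_range,
                 class_params = class_params),
            class = "population_config")
}

# A compact blob of unique integer pixels around a center.
make_segment_mask <- function(center, n_pixels, field_size) {
  r <- ceiling(sqrt(n_pixels / pi)) + 2
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  offs <- offs[order(offs$dr^2 + offs$dc^2), ]
  px <- cbind(round(center[1]) + offs$dr, round(center[2]) + offs$dc)
  px <- px[seq_len(min(n_pixels, nrow(px))), , drop = FALSE]
  px[, 1] <- pmin(pmax(px[, 1], 0), field_size[1] - 1)
  px[, 2] <- pmin(pmax(px[, 2], 0), field_size[2] - 1)
  unique(px)
}

#' Generate a ground-truth axon population
#'
#' Draws per-axon class labels, whisker selectivity (`true_wsi`), response
#' latency, event amplitude (in noise-SD units), lick-transient gain and
#' lick-trial gain modulation, spatial layout, segment masks, drift
#' coefficients, noise level and neuropil coefficient. VPM-like tuned axons
#' are laid out in two spatially disjoint clusters (C2-preferring vs
#' B2-preferring); POm-like axons are intermingled.
#'
#' @param pop_cfg a [population_config()].
#' @param seed integer seed.
#' @return list of axon-spec lists (class `ground_truth`), each with fields
#'   `axon_id`, `class`, `true_wsi`, `true_latency`, `event_amplitude`,
#'   `lick_transient_gain`, `lick_gain_modulation`, `n_segments`,
#'   `segment_masks`, `centroid`, `drift_coefficients`, `noise_sd`,
#'   `neuropil_coefficient`, `segment_correlation`.
#' @export
generate_axon_population <- function(pop_cfg = population_config(), seed = 1L) {
  stopifnot(inherits(pop_cfg, "population_config"))
  set.seed(seed)
  n <- pop_cfg$n_axons
  classes <- sample(names(pop_cfg$class_proportions), n, replace = TRUE,
                    prob = pop_cfg$class_proportions)
  fs <- pop_cfg$field_size
  cluster_centers <- list(C2 = c(0.5 * fs[1], 0.3 * fs[2]),
                          B2 = c(0.5 * fs[1], 0.7 * fs[2]))
  axons <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- pop_cfg$class_params[[classes[i]]]
    wsi_abs <- stats::runif(1, cp$wsi_abs[1], cp$wsi_abs[2])
    wsi_sign <- if (cp$bimodal) sample(c(-1, 1), 1) else sample(c(-1, 1), 1)
    true_wsi <- wsi_sign * wsi_abs
    if (cp$clustered) {
      ctr <- if (true_wsi >= 0) cluster_centers$C2 else cluster_centers$B2
      centroid <- ctr + stats::rnorm(2, 0, 0.05 * fs[1])
    } else {
      centroid <- c(0.5 * fs[1], 0.5 * fs[2]) + stats::rnorm(2, 0, 0.18 * fs[1])
    }
    centroid <- pmin(pmax(centroid, 10), fs - 10)
    n_seg <- sample(seq(pop_cfg$n_segments_range[1],
                        pop_cfg$n_segments_range[2]), 1)
    masks <- lapply(seq_len(n_seg), function(s) {
      ctr_s <- pmin(pmax(centroid + stats::rnorm(2, 0, 12), 5), fs - 5)
      make_segment_mask(ctr_s,
                        sample(seq(pop_cfg$pixels_per_segment[1],
                                   pop_cfg$pixels_per_segment[2]), 1),
                        fs)
    })
    axons[[i]] <- list(
      axon_id = i,
      class = classes[i],
      true_wsi = true_wsi,
      true_latency = stats::runif(1, cp$latency[1], cp$latency[2]),
      event_amplitude = stats::runif(1, cp$amplitude[1], cp$amplitude[2]),
      lick_transient_gain = stats::runif(1, cp$lick_transient_gain[1],
                                         cp$lick_transient_gain[2]),
      lick_gain_modulation = stats::runif(1, cp$lick_gain_modulation[1],
                                          cp$lick_gain_modulation[2]),
      n_segments = n_seg,
      segment_masks = masks,
      centroid = centroid,
      drift_coefficients = stats::runif(3, -pop_cfg$drift_amplitude,
                                        pop_cfg$drift_amplitude),
      noise_sd = stats::runif(1, pop_cfg$noise_sd_range[1],
                              pop_cfg$noise_sd_range[2]),
      neuropil_coefficient = stats::runif(1,
                                          pop_cfg$neuropil_coefficient_range[1],
                                          pop_cfg$neuropil_coefficient_range[2]),
      segment_correlation = pop_cfg$segment_correlation,
      amplitude_cv = pop_cfg$amplitude_cv
    )
  }
  structure(axons, class = "ground_truth")
}

#' Ground truth as a data.frame
#'
#' @param truth a `ground_truth` list from [generate_axon_population()].
#' @return one row per axon with the scalar ground-truth fields.
#' @export
ground_truth_table <- function(truth) {
  do.call(rbind, lapply(truth, function(a) {
    data.frame(axon_id = a$axon_id, class = a$class, true_wsi = a$true_wsi,
               true_latency = a$true_latency,
               event_amplitude = a$event_amplitude,
               lick_transient_gain = a$lick_transient_gain,
               lick_gain_modulation = a$lick_gain_modulation,
               n_segments = a$n_segments, noise_sd = a$noise_sd,
               neuropil_coefficient = a$neuropil_coefficient,
               centroid_row = a$centroid[1], centroid_col = a$centroid[2],
               stringsAsFactors = FALSE)
  }))
}

# Condition amplitudes from the selectivity index: A_C2 = A (1 + wsi) / 2,
# A_B2 = A (1 - wsi) / 2, so the WSI of noiseless amplitudes is exactly wsi.
wsi_condition_amplitudes <- function(amplitude, wsi) {
  c(C2 = amplitude * (1 + wsi) / 2, B2 = amplitude * (1 - wsi) / 2)
}

#' Synthesize ROI-segment fluorescence traces
#'
#' Forward model for one session. Per axon: whisker-evoked calcium events at
#' `stim_onset + true_latency` with condition amplitudes
#' `A (1 +/- true_wsi)/2` (times the lick gain modulation in lick trials),
#' plus lick-locked events at the reaction time for axons with a lick
#' transient gain, all convolved with the GCaMP6s kernel; a slow polynomial
#' baseline drift; shared session neuropil; and Gaussian noise split into a
#' shared and a per-segment independent component so that segments of one
#' axon correlate at the configured level. Event amplitudes carry a per-trial
#' multiplicative gamma jitter (mean 1, CV `amplitude_cv`), independent across
#' axons.
#'
#' Event amplitudes are expressed in units of the axon's noise SD; for
#' noiseless axons (`noise_sd = 0`) the unit is 1 fluorescence unit.
#'
#' @param truth a `ground_truth` population.
#' @param trials trial table from [generate_trial_schedule()].
#' @param cfg the [session_config()].
#' @param seed integer seed for noise, jitter and neuropil.
#' @param baseline_offset raw fluorescence offset added to every trace.
#' @param neuropil_baseline,neuropil_amplitudes,neuropil_noise_sd level, slow
#'   sinusoid amplitudes and fast noise SD of the shared neuropil trace,
#'   fluorescence units.
#' @return list of ROI segments, each a list with `segment_id`,
#'   `parent_axon_id`, `pixel_mask` (n x 2 integer matrix), `raw_trace`,
#'   `neuropil_trace`, `neuropil_coefficient`.
#' @export
synthesize_traces <- function(truth, trials, cfg, seed = 1L,
                              baseline_offset = 100,
                              neuropil_baseline = 20,
                              neuropil_amplitudes = c(1.5, 1),
                              neuropil_noise_sd = 0.3) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "session_config"))
  set.seed(seed)
  n_frames <- cfg$n_trials * cfg$frames_per_trial
  fr <- cfg$frame_rate
  kern <- gcamp_kernel(fr)
  u <- (seq_len(n_frames) - 1) / max(n_frames - 1, 1)

  # Shared session neuropil: smooth multi-sinusoid plus small noise.
  t_all <- (seq_len(n_frames) - 1) / fr
  neuropil <- neuropil_baseline +
    neuropil_amplitudes[1] * sin(2 * pi * t_all / 311 + stats::runif(1, 0, 2 * pi)) +
    neuropil_amplitudes[2] * sin(2 * pi * t_all / 97 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n_frames, 0, neuropil_noise_sd)

  max_lat <- max(vapply(truth, `[[`, numeric(1), "true_latency"))
  if (max_lat >= cfg$trial_duration - cfg$quiet_window)
    stop("true_latency extends beyond the trial end", call. = FALSE)

  segments <- list()
  for (a in truth) {
    impulses <- numeric(n_frames)
    amps <- wsi_condition_amplitudes(a$event_amplitude, a$true_wsi)
    unit <- if (a$noise_sd > 0) a$noise_sd else 1
    cv <- if (is.null(a$amplitude_cv)) 0 else a$amplitude_cv
    jitter <- if (cv > 0)
      stats::rgamma(nrow(trials), shape = 1 / cv^2, rate = 1 / cv^2)
    else rep(1, nrow(trials))
    for (k in seq_len(nrow(trials))) {
      cond <- trials$condition[k]
      onset <- trials$stim_onset_frame[k]
      if (cond %in% c("C2", "B2")) {
        f <- onset + round(a$true_latency * fr)
        gain <- if (isTRUE(trials$lick[k])) a$lick_gain_modulation else 1
        impulses[f + 1L] <- impulses[f + 1L] +
          amps[[cond]] * gain * jitter[k] * unit
      }
      if (isTRUE(trials$lick[k]) && a$lick_transient_gain > 0) {
        f <- onset + round(trials$reaction_time_s[k] * fr)
        if (f < n_frames)
          impulses[f + 1L] <- impulses[f + 1L] +
            a$lick_transient_gain * jitter[k] * unit
      }
    }
    # sparse convolution with the kernel: exact, and fast for sparse events
    signal <- numeric(n_frames)
    for (f in which(impulses != 0)) {
      span <- f:min(n_frames, f + length(kern) - 1L)
      signal[span] <- signal[span] + impulses[f] * kern[seq_along(span)]
    }
    drift <- as.vector(cbind(u, u^2, u^3) %*% a$drift_coefficients)

    rho <- a$segment_correlation
    shared <- stats::rnorm(n_frames, 0, a$noise_sd * sqrt(rho))
    axon_common <- baseline_offset + drift + signal + shared
    for (s in seq_len(a$n_segments)) {
      indep <- stats::rnorm(n_frames, 0, a$noise_sd * sqrt(1 - rho))
      segments[[length(segments) + 1L]] <- list(
        segment_id = sprintf("ax%03d_seg%d", a$axon_id, s),
        parent_axon_id = a$axon_id,
        pixel_mask = a$segment_masks[[s]],
        raw_trace = axon_common + indep + a$neuropil_coefficient * neuropil,
        neuropil_trace = neuropil,
        neuropil_coefficient = a$neuropil_coefficient
      )
    }
  }
  segments
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: trial schedule, ground-truth axon population and
#' ROI-segment traces from one master seed (sub-seeds are derived from it so
#' the session is bit-reproducible).
#'
#' @param cfg a [session_config()]; its `seed` is overridden by `seed`.
#' @param beh a [behavior_config()].
#' @param pop_cfg a [population_config()].
#' @param seed master integer seed.
#' @return list with `config`, `behavior`, `trials`, `truth`, `segments`.
#' @export
simulate_session <- function(cfg = session_config(),
                             beh = behavior_config(),
                             pop_cfg = population_config(),
                             seed = 1L) {
  seed <- as.integer(seed)
  cfg$seed <- seed
  trials <- generate_trial_schedule(cfg, beh)
  truth <- generate_axon_population(pop_cfg, seed = seed + 1L)
  segments <- synthesize_traces(truth, trials, cfg, seed = seed + 2L)
  list(config = cfg, behavior = beh, trials = trials, truth = truth,
       segments = segments)
}
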