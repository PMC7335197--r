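# Shared fixtures, all built in code.

# Minimal ROI segment.
make_segment <- function(trace, id = "s1", n_pixels = 1,
                         neuropil = rep(0, length(trace)), coef = 0) {
  px <- cbind(seq_len(n_pixels), rep(1L, n_pixels))
  list(segment_id = id, parent_axon_id = NA, pixel_mask = px,
       raw_trace = trace, neuropil_trace = neuropil,
       neuropil_coefficient = coef)
}

# Traces with an exact sample correlation matrix R: zero-mean orthonormal
# columns mixed by the Cholesky factor of R.
exact_corr_traces <- function(R, n_frames = 300, seed = 1) {
  set.seed(seed)
  k <- nrow(R)
  M <- matrix(rnorm(n_frames * k), n_frames, k)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  X <- Q %*% chol(R)
  sweep(X, 2, apply(X, 2, sd), "/")
}

# Single-axon ground truth with explicit knobs; defaults give a clean
# noise-free forward model.
single_axon_truth <- function(true_wsi = 0, true_latency = 0.1,
                              event_amplitude = 2, lick_transient_gain = 0,
                              lick_gain_modulation = 1, n_segments = 1,
                              noise_sd = 0, drift = c(0, 0, 0),
                              neuropil_coefficient = 0, amplitude_cv = 0,
                              segment_correlation = 0.9) {
  masks <- lapply(seq_len(n_segments), function(s)
    cbind(10L + s, 10L))
  structure(list(list(
    axon_id = 1L, class = "custom", true_wsi = true_wsi,
    true_latency = true_latency, event_amplitude = event_amplitude,
    lick_transient_gain = lick_transient_gain,
    lick_gain_modulation = lick_gain_modulation, n_segments = n_segments,
    segment_masks = masks, centroid = c(10, 10),
    drift_coefficients = drift, noise_sd = noise_sd,
    neuropil_coefficient = neuropil_coefficient,
    segment_correlation = segment_correlation,
    amplitude_cv = amplitude_cv
  )), class = "ground_truth")
}

# Hand-written trial table (for pipeline/statistics tests).
manual_trials <- function(condition, lick, reaction_time_s = NULL, cfg) {
  n <- length(condition)
  if (is.null(reaction_time_s)) reaction_time_s <- ifelse(lick, 0.3, NA)
  data.frame(
    trial = seq_len(n), condition = condition,
    stim_onset_frame = (seq_len(n) - 1L) * cfg$frames_per_trial +
      cfg$stim_onset_within_trial,
    onset_time_s = (seq_len(n) - 1) * (cfg$trial_duration +
                                         cfg$min_intertrial_gap) +
      cfg$quiet_window,
    lick = lick, reaction_time_s = reaction_time_s,
    outcome = ifelse(condition == "C2", ifelse(lick, "hit", "miss"),
              ifelse(condition == "B2",
                     ifelse(lick, "false_alarm", "correct_rejection"),
                     ifelse(lick, "no_stim_lick", "no_stim_quiet"))),
    stringsAsFactors = FALSE
  )
}

# Ellipse_fit with given center, semi-axes and rotation (for geometry tests).
make_ellipse <- function(center, semi_axes, angle = 0, confidence = 0.9) {
  Rm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  structure(list(center = center, covariance = NA, confidence = confidence,
                 semi_axes = semi_axes, orientation = Rm,
                 area = pi * prod(semi_axes)),
            class = "ellipse_fit")
}

# Monte-Carlo area of the intersection of two ellipse_fits by rejection
# sampling. The intersection is contained in either ellipse, so sampling the
# bounding box of the smaller one keeps the estimator variance low.
# Independent oracle for the polygon-clipping route.
mc_intersection_area <- function(e1, e2, n_points = 1e6, seed = 1) {
  set.seed(seed)
  small <- if (prod(e1$semi_axes) <= prod(e2$semi_axes)) e1 else e2
  r <- max(small$semi_axes)
  xl <- small$center[1] - r; xu <- small$center[1] + r
  yl <- small$center[2] - r; yu <- small$center[2] + r
  x <- runif(n_points, xl, xu); y <- runif(n_points, yl, yu)
  inside <- function(e) {
    d <- rbind(x - e$center[1], y - e$center[2])
    u <- t(e$orientation) %*% d
    (u[1, ] / e$semi_axes[1])^2 + (u[2, ] / e$semi_axes[2])^2 <= 1
  }
  mean(inside(e1) & inside(e2)) * (xu - xl) * (yu - yl)
}

# Cluster labels from a merge_partition, for partition-recovery checks.
partition_labels <- function(partition, n_segments) {
  lab <- rep(NA_integer_, n_segments)
  for (i in seq_along(partition$clusters)) lab[partition$clusters[[i]]] <- i
  lab
}
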