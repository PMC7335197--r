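test_that("baseline estimator recovers constants and exact polynomials", {
  expect_equal(suppressWarnings(estimate_baseline(rep(4.2, 5000))),
               rep(4.2, 5000))

  # a cubic is inside the span of the 5th-order fit; the remaining error is
  # the mode discretization within each 3000-frame segment. For noiseless
  # monotone data the value-distribution mode sits at the flattest point of
  # each segment, not at its center, which bounds the half-sample-mode error
  # by the within-segment signal excursion (~a tenth of the range here).
  n <- 30000
  u <- (seq_len(n) - 1) / (n - 1)
  trace <- 2 + 3 * u - 5 * u^2 + 4 * u^3
  b <- estimate_baseline(trace)
  expect_lt(max(abs(b - trace)), 0.15 * diff(range(trace)))

  # with symmetric noise the segment mode recenters on the polynomial; at
  # session scale (30 mode points) the fit averages the mode scatter out
  set.seed(31)
  n2 <- 90000
  u2 <- (seq_len(n2) - 1) / (n2 - 1)
  cubic2 <- 2 + 3 * u2 - 5 * u2^2 + 4 * u2^3
  noisy <- cubic2 + rnorm(n2)
  expect_lt(sqrt(mean((estimate_baseline(noisy) - cubic2)^2)), 0.15)
})

test_that("baseline tracks drift despite sparse positive transients and noise", {
  set.seed(21)
  n <- 90000
  drift <- seq(0, 10, length.out = n)
  trace <- drift + rnorm(n)
  events <- sample(n, round(0.05 * n))
  trace[events] <- trace[events] + abs(rnorm(length(events), 6, 2))
  b <- estimate_baseline(trace)
  expect_lt(sqrt(mean((b - drift)^2)), 0.15)
})

test_that("baseline is invariant to transient amplitude (mode robustness)", {
  set.seed(22)
  n <- 30000
  trace <- rnorm(n)
  events <- sample(n, round(0.05 * n))
  tr_small <- trace; tr_small[events] <- tr_small[events] + 5
  tr_huge <- trace; tr_huge[events] <- tr_huge[events] + 5000
  expect_equal(estimate_baseline(tr_small), estimate_baseline(tr_huge),
               tolerance = 0.05)
})

test_that("polynomial order is reduced with a warning on short traces", {
  expect_warning(estimate_baseline(rnorm(6000), poly_order = 5),
                 "order reduced")
})

test_that("noise SD comes from negative fluctuations only", {
  expect_equal(suppressWarnings(estimate_noise_sd(rep(c(-1, 1000), 50))), 1)

  set.seed(5)
  r <- rnorm(1e5, 0, 2.5)
  expect_lt(abs(estimate_noise_sd(r) / 2.5 - 1), 0.02)

  # positive-side contamination does not matter
  contaminated <- c(rnorm(5e4, 0, 1), abs(rnorm(5e4, 0, 8)))
  expect_lt(abs(estimate_noise_sd(contaminated) - 1), 0.03)

  expect_error(estimate_noise_sd(rep(1, 100)), "negative")
})

test_that("normalization is self-consistent and recovers configured noise", {
  set.seed(9)
  trace <- rnorm(3e4)
  nt <- normalize_trace(trace)
  expect_lt(abs(sd(nt$normalized) - 1), 0.05)

  # shift and positive scaling leave the normalized trace unchanged
  nt_shift <- normalize_trace(trace + 55)
  expect_equal(nt$normalized, nt_shift$normalized, tolerance = 1e-8)
  nt_scale <- normalize_trace(trace * 7)
  expect_equal(nt$normalized, nt_scale$normalized, tolerance = 1e-8)

  # ground-truth noise recovery through the merged-axon path
  n_trials <- 120
  cfg <- session_config(n_trials = n_trials, seed = 1)
  truth <- single_axon_truth(event_amplitude = 4, true_wsi = 0.3,
                             noise_sd = 1.1, n_segments = 2,
                             drift = c(2, -3, 1), neuropil_coefficient = 0.6,
                             amplitude_cv = 0.7)
  trials <- generate_trial_schedule(cfg)
  segs <- synthesize_traces(truth, trials, cfg, seed = 2)
  m <- merge_segments(segs, correlation_cluster(segs))
  expect_length(m, 1)
  nt2 <- normalize_trace(m[[1]])
  expect_lt(abs(nt2$noise_sd / 1.1 - 1), 0.05)
})

test_that("trial z-score normalizes the pre-window and groups by condition x lick", {
  cfg <- session_config(n_trials = 40, seed = 13)
  trials <- generate_trial_schedule(cfg)
  truth <- single_axon_truth(event_amplitude = 5, true_wsi = 0.2,
                             noise_sd = 1, amplitude_cv = 0.5)
  segs <- synthesize_traces(truth, trials, cfg, seed = 13)
  nt <- suppressWarnings(
    normalize_trace(merge_segments(segs, correlation_cluster(segs))[[1]]))
  tens <- trial_zscore(nt, trials, cfg)

  expect_equal(tens$bin_period, 1 / cfg$frame_rate)
  for (g in tens$groups) {
    pre <- g$z[, seq_len(tens$n_pre), drop = FALSE]
    expect_equal(mean(pre), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(pre)), 1, tolerance = 1e-10)
  }
  # groups partition the usable trials
  all_tr <- unlist(lapply(tens$groups[grepl("\\.all$", names(tens$groups))],
                          `[[`, "trials"))
  expect_setequal(all_tr, trials$trial)
})

test_that("null axon bin means scale as 1/sqrt(n_trials)", {
  cfg <- session_config(n_trials = 80, seed = 17)
  trials <- generate_trial_schedule(cfg)
  truth <- single_axon_truth(event_amplitude = 0, noise_sd = 1)
  segs <- synthesize_traces(truth, trials, cfg, seed = 17)
  nt <- normalize_trace(merge_segments(segs, correlation_cluster(segs))[[1]])
  tens <- trial_zscore(nt, trials, cfg)
  g <- tens$groups[["C2.all"]]
  post <- g$z[, tens$time >= 0, drop = FALSE]
  bin_means <- colMeans(post)
  # ~210 bins: sd of the bin means should be close to 1/sqrt(n)
  expect_lt(abs(sd(bin_means) * sqrt(nrow(post)) - 1), 0.25)
})

test_that("zero-variance pre-window invalidates the group with a warning", {
  cfg <- session_config(n_trials = 4, seed = 1)
  trials <- manual_trials(rep("C2", 4), rep(FALSE, 4), cfg = cfg)
  nt <- structure(list(axon_id = 1,
                       baseline_curve = numeric(4 * cfg$frames_per_trial),
                       noise_sd = 1,
                       normalized = rep(0, 4 * cfg$frames_per_trial)),
                  class = "normalized_trace")
  w <- capture_warnings(tens <- trial_zscore(nt, trials, cfg))
  expect_true(any(grepl("zero pre-window SD", w)))
  expect_length(tens$groups, 0)
})
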