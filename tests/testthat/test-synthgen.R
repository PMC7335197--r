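test_that("trial scheduler respects timing, proportions and truncation", {
  cfg <- session_config(n_trials = 200, seed = 11)
  beh <- behavior_config()
  tr <- generate_trial_schedule(cfg, beh)

  # inter-onset gaps never below trial_duration + min gap; floor is attained
  isi <- diff(tr$onset_time_s)
  expect_true(all(isi >= cfg$trial_duration + cfg$min_intertrial_gap - 1e-12))
  expect_equal(min(isi), 13.5)

  # reaction times live in (0, response_window]
  rts <- tr$reaction_time_s[tr$lick]
  expect_true(all(rts > 0 & rts <= cfg$response_window))
  expect_true(all(is.na(tr$reaction_time_s[!tr$lick])))

  # outcomes follow the task contingencies
  expect_true(all(tr$outcome[tr$condition == "C2" & tr$lick] == "hit"))
  expect_true(all(tr$outcome[tr$condition == "B2" & !tr$lick] ==
                    "correct_rejection"))

  # degenerate stimulus mix
  cfg0 <- session_config(n_trials = 50, stim_fraction = 0, seed = 1)
  expect_true(all(generate_trial_schedule(cfg0, beh)$condition == "none"))

  # stimulus fraction concentrates at its configured value
  cfgN <- session_config(n_trials = 10000, seed = 5)
  trN <- generate_trial_schedule(cfgN, beh)
  frac <- mean(trN$condition != "none")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
})

test_that("trial schedule and traces are reproducible from the seed", {
  cfg <- session_config(n_trials = 30, seed = 7)
  s1 <- simulate_session(cfg, pop_cfg = population_config(n_axons = 4), seed = 7)
  s2 <- simulate_session(cfg, pop_cfg = population_config(n_axons = 4), seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$segments[[1]]$raw_trace, s2$segments[[1]]$raw_trace)
  expect_identical(ground_truth_table(s1$truth), ground_truth_table(s2$truth))
})

test_that("stimulus waveform has exact support and zero-mean pulses", {
  cfg <- session_config(seed = 1)
  w <- synthesize_stimulus_waveform(cfg, sample_rate = 1000)
  dt <- 1 / 1000
  expect_equal(sum(w$displacement != 0) * dt, 0.2)

  cfg1 <- session_config(n_pulses = 1, stim_duration = 0.04, seed = 1)
  w1 <- synthesize_stimulus_waveform(cfg1, sample_rate = 1000)
  expect_equal(sum(w1$displacement != 0) * dt, 0.04)

  # each full-period sine pulse integrates to ~0
  for (k in 0:4) {
    pulse <- w$displacement[w$time >= k * 0.04 & w$time < (k + 1) * 0.04]
    expect_lt(abs(sum(pulse) * dt), 1e-12)
  }
})

test_that("axon population reflects class proportions and tuning structure", {
  pop_vpm <- population_config(n_axons = 40,
                               class_proportions = c(VPM_like = 1,
                                                     POmFO_like = 0,
                                                     POmHO_like = 0))
  truth <- generate_axon_population(pop_vpm, seed = 2)
  tab <- ground_truth_table(truth)
  expect_true(all(tab$class == "VPM_like"))

  pop_ho <- population_config(n_axons = 40,
                              class_proportions = c(VPM_like = 0,
                                                    POmFO_like = 0,
                                                    POmHO_like = 1))
  tab_ho <- ground_truth_table(generate_axon_population(pop_ho, seed = 2))
  expect_lt(mean(abs(tab_ho$true_wsi)), mean(abs(tab$true_wsi)))

  # determinism
  t2 <- generate_axon_population(pop_vpm, seed = 2)
  expect_identical(ground_truth_table(truth), ground_truth_table(t2))

  expect_error(population_config(n_axons = 0), "at least one axon")
  expect_error(population_config(class_proportions = c(VPM_like = 0.5,
                                                       POmFO_like = 0.1,
                                                       POmHO_like = 0.1)),
               "sum to 1")
})

test_that("noiseless forward model reproduces the kernel at the event time", {
  cfg <- session_config(n_trials = 1, seed = 1)
  truth <- single_axon_truth(true_wsi = 0, true_latency = 0.1,
                             event_amplitude = 2)
  trials <- manual_trials("C2", FALSE, cfg = cfg)
  segs <- synthesize_traces(truth, trials, cfg, seed = 1,
                            baseline_offset = 0,
                            neuropil_amplitudes = c(0, 0),
                            neuropil_noise_sd = 0)
  tr <- segs[[1]]$raw_trace
  onset <- trials$stim_onset_frame[1] + round(0.1 * cfg$frame_rate)
  kern <- gcamp_kernel(cfg$frame_rate)
  # amplitude 1 per (1+wsi)/2 rule with wsi=0, amplitude 2
  n_k <- min(length(kern), length(tr) - onset)
  expect_equal(tr[onset + seq_len(n_k)], kern[seq_len(n_k)], tolerance = 1e-12)
  expect_true(all(tr[seq_len(onset)] == 0))
  expect_lte(abs(which.max(tr) - (onset + which.max(kern))), 1)
})

test_that("fully selective axon gives zero B2-evoked amplitude", {
  cfg <- session_config(n_trials = 2, seed = 1)
  truth <- single_axon_truth(true_wsi = 1, event_amplitude = 2)
  # B2 trial first so the C2 kernel tail cannot spill into it
  trials <- manual_trials(c("B2", "C2"), c(FALSE, FALSE), cfg = cfg)
  segs <- synthesize_traces(truth, trials, cfg, seed = 1, baseline_offset = 0,
                            neuropil_amplitudes = c(0, 0),
                            neuropil_noise_sd = 0)
  tr <- segs[[1]]$raw_trace
  expect_true(all(tr[seq_len(cfg$frames_per_trial)] == 0))
  expect_gt(max(tr[-seq_len(cfg$frames_per_trial)]), 0)
})

test_that("within-axon segment correlation matches the variance-split target", {
  cfg <- session_config(n_trials = 200, seed = 3)  # 54,000 frames
  truth <- single_axon_truth(event_amplitude = 0, noise_sd = 1,
                             n_segments = 2, segment_correlation = 0.9)
  trials <- manual_trials(rep("none", 200), rep(FALSE, 200), cfg = cfg)
  segs <- synthesize_traces(truth, trials, cfg, seed = 4, baseline_offset = 0,
                            neuropil_amplitudes = c(0, 0),
                            neuropil_noise_sd = 0)
  r <- cor(segs[[1]]$raw_trace, segs[[2]]$raw_trace)
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("transient-free trace noise matches the configured SD within 2%", {
  # 1e5 frames
  n_trials <- 371
  cfg <- session_config(n_trials = n_trials, seed = 3)
  truth <- single_axon_truth(event_amplitude = 0, noise_sd = 1.3)
  trials <- manual_trials(rep("none", n_trials), rep(FALSE, n_trials), cfg = cfg)
  segs <- synthesize_traces(truth, trials, cfg, seed = 9, baseline_offset = 0,
                            neuropil_amplitudes = c(0, 0),
                            neuropil_noise_sd = 0)
  expect_lt(abs(sd(segs[[1]]$raw_trace) / 1.3 - 1), 0.02)
})

test_that("configuration and generation errors are raised", {
  expect_error(session_config(trial_duration = 3), "must exceed")
  expect_error(session_config(stim_fraction = 1.2), "stim_fraction")
  expect_error(session_config(n_pulses = 4), "pulse_duration")
  expect_error(behavior_config(p_lick = c(C2 = 1.5, B2 = 0.3, none = 0.1)),
               "probabilities")
  cfg <- session_config(n_trials = 1, seed = 1)
  truth <- single_axon_truth(true_latency = 8)
  trials <- manual_trials("C2", FALSE, cfg = cfg)
  expect_error(synthesize_traces(truth, trials, cfg, seed = 1),
               "beyond the trial end")
})
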