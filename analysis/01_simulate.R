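#!/usr/bin/env Rscript
# Simulate a demo imaging session of the two-whisker discrimination task:
# 200 trials (80% whisker stimuli, split C2/B2), 50 thalamocortical axons in
# three classes, trial-based 30 Hz acquisition. Writes the trial table and
# ground truth; later scripts re-derive the same session from the seed rather
# than serializing raw traces.

library(thalaxon)

seed <- 42L
dir.create("results", showWarnings = FALSE)

cfg <- session_config(n_trials = 200, seed = seed)
beh <- behavior_config()
pop <- population_config(n_axons = 50)
session <- simulate_session(cfg, beh, pop, seed = seed)

perf <- session_performance(session$trials)
cat(sprintf("Simulated %d trials, %d axons (%d ROI segments)\n",
            nrow(session$trials), length(session$truth),
            length(session$segments)))
cat(sprintf("Behavioral performance: %.3f -> session %s\n", perf,
            if (session_included(perf)) "included (> 0.6)" else "excluded"))
print(table(session$trials$outcome))

rts <- session$trials$reaction_time_s
cat(sprintf("First-lick reaction time: %.2f +/- %.2f s (mean +/- SD, n = %d)\n",
            mean(rts, na.rm = TRUE), sd(rts, na.rm = TRUE), sum(!is.na(rts))))

write.csv(session$trials, "results/trials.csv", row.names = FALSE)
write.csv(ground_truth_table(session$truth), "results/ground_truth.csv",
          row.names = FALSE)
cat("wrote results/trials.csv and results/ground_truth.csv\n")
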