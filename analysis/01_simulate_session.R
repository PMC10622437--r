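#!/usr/bin/env Rscript
# Simulate the reference synthetic session used throughout the analysis:
# a miniscope-scale population (60 units, 150 trials at 20 Hz) with
# phase-tuned subpopulations, a planted delay-period sequence, and a
# 70-80% correct-choice rate. Writes the session to scratch/session/ and
# a small behavioral summary.

library(wmtrace)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
cfg <- session_config(seed = 1234)
sess <- simulate_session(cfg)

stopifnot(nrow(validate_events(sess$events)) == 0)
write_session(sess, "scratch/session")

perf <- mean(sess$events$outcome == "correct")
durs <- as.matrix(sess$events[sprintf("t_event_%02d", 2:11)]) -
  as.matrix(sess$events[sprintf("t_event_%02d", 1:10)])
summary <- data.frame(
  n_trials = cfg$n_trials,
  n_units = cfg$n_units,
  rate_hz = cfg$rate,
  fraction_correct = perf,
  median_trial_s = median(rowSums(durs, na.rm = TRUE)),
  median_maintenance_s = median(sess$events$t_event_07 -
                                  sess$events$t_event_05)
)
write.csv(summary, "results/01_behavior_summary.csv", row.names = FALSE)

cat(sprintf("Simulated %d trials (%.0f%% correct), %d units; median trial %.1f s, median delay-period %.1f s.\n",
            cfg$n_trials, 100 * perf, cfg$n_units,
            summary$median_trial_s, summary$median_maintenance_s))
cat("Session written to scratch/session/.\n")
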