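#!/usr/bin/env Rscript
# Transient population encoding: per-bin L2 distance between
# condition-averaged population vectors with a label-permutation null
# (left vs right sample side; correct vs mistake per side), plus per-unit
# predictive fractions per task period with their binomial window test.

library(wmtrace)

sess <- read_session("scratch/session")
ad <- build_aligned_tensor(sess$events, sess$deconv,
                           signal = "deconvolved")

# left vs right on correct trials
keep <- which(sess$events$outcome == "correct")
tens <- ad
tens$values <- ad$values[keep, , , drop = FALSE]
tens$labels <- ad$labels[keep, , drop = FALSE]
dec_side <- l2_permutation_test(tens, tens$labels$side, n_perm = 1000,
                                seed = 1234)
phase_of_bin <- rep(ad$phases, diff(ad$boundaries))
write.csv(data.frame(bin = dec_side$t,
                     period = wm_period_of_phase(phase_of_bin),
                     l2 = dec_side$l2, p = dec_side$p,
                     neg_log10_p = dec_side$neg_log10_p),
          "results/07_decode_side.csv", row.names = FALSE)

sig_per_period <- tapply(dec_side$p <= 0.01,
                         wm_period_of_phase(phase_of_bin), mean)
cat("Left-vs-right L2 decoding: fraction of bins at p <= 0.01 per period:\n")
print(round(sig_per_period, 3))

# correct vs mistake, separately per sample side
for (s in c("left", "right")) {
  sel <- which(sess$events$side == s)
  tens <- ad
  tens$values <- ad$values[sel, , , drop = FALSE]
  tens$labels <- ad$labels[sel, , drop = FALSE]
  dec <- l2_permutation_test(tens, tens$labels$outcome, n_perm = 1000,
                             seed = 1234 + match(s, c("left", "right")))
  write.csv(data.frame(bin = dec$t, l2 = dec$l2, p = dec$p,
                       neg_log10_p = dec$neg_log10_p),
            sprintf("results/07_decode_outcome_%s.csv", s),
            row.names = FALSE)
}

# per-unit predictive fractions for the side contrast, per period
m <- window_mean_activity(sess$events, sess$deconv, windows = "periods")
pf <- predictive_unit_fraction(m, sess$events$side[keep])
write.csv(pf, "results/07_predictive_fractions.csv", row.names = FALSE)
cat("Fraction of units predictive of sample side per period:\n")
print(pf, row.names = FALSE)
cat("Decoding tables written to results/07_*.csv.\n")
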