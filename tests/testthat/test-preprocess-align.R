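# One hand-built two-trial session: a single unit sampled at 10 Hz with
# known phase durations, so baseline windows and phase segments are exact.
toy_session <- function(values, rate = 10, durations = rep(2, 10),
                        lead = 3) {
  ev <- lead + c(0, cumsum(durations))
  events <- data.frame(trial_id = 1L, session_id = "toy",
                       side = "left", outcome = "correct")
  events[event_cols_pub()] <- as.list(ev)
  list(events = events,
       trace = trace_block(matrix(values, nrow = 1), rate = rate))
}
event_cols_pub <- function() sprintf("t_event_%02d", 1:11)

test_that("dff matches the percentage-change formula", {
  # constant trace: dff identically zero
  toy <- toy_session(rep(4, 300))
  d <- compute_dff(toy$trace, toy$events[1, ])
  expect_true(all(d$values == 0))
  # F0 = 2 in the pre-maintenance baseline, F = 3 after event 5: 50%
  v <- rep(2, 300); v[111:230] <- 3  # maintenance onward (event 5 at t=11)
  toy <- toy_session(v)
  d <- compute_dff(toy$trace, toy$events[1, ])
  expect_setequal(unique(as.numeric(d$values)), c(0, 50))
  expect_equal(as.numeric(d$values)[81:200], rep(50, 120))
  # ramp trace against the elementwise formula
  v <- seq(0.5, 3.5, length.out = 300)
  toy <- toy_session(v)
  d <- compute_dff(toy$trace, toy$events[1, ])
  f0 <- mean(v[101:110])  # 1-s baseline before event 5 (t in [10, 11))
  expect_equal(as.numeric(d$values), (v[31:230] - f0) / f0 * 100)
  expect_error(compute_dff(trace_block(matrix(0, 1, 300), rate = 10),
                           toy$events[1, ]), "F0 = 0")
})

test_that("z-scoring uses per-trial baseline mean and sample sd", {
  # baseline samples {1,3}: F0 = 2, sample sd = sqrt(2); F = 4 -> z = sqrt(2)
  # 2 Hz sampling puts exactly two bins in the 1-s baseline window
  v <- rep(2, 300)
  v[45] <- 1; v[46] <- 3  # window [22, 23) before event 5 at t = 23
  v[47:300] <- 4
  toy <- toy_session(v, rate = 2, durations = rep(5, 10))
  z <- zscore_trial(toy$trace, toy$events[1, ])
  expect_equal(z$values[1, ncol(z$values)], sqrt(2), tolerance = 1e-12)
  b <- trial_baseline(toy$trace, toy$events[1, ])
  expect_equal(b$F0[1], 2)
  expect_equal(b$sigma[1], sqrt(2))
  # affine invariance: F -> aF + b leaves z unchanged
  toy2 <- toy_session(3.7 * v + 11, rate = 2, durations = rep(5, 10))
  z2 <- zscore_trial(toy2$trace, toy2$events[1, ])
  expect_equal(z2$values, z$values, tolerance = 1e-10)
  # constant baseline is an error, not infinities
  expect_error(zscore_trial(trace_block(matrix(1, 1, 300), rate = 10),
                            toy$events[1, ]), "sigma = 0")
})

test_that("median phase durations follow the sort-and-pick oracle", {
  cfg <- tiny_cfg(n_trials = 31, p_mistake = 0.3)
  ev <- generate_events(cfg)
  med <- median_phase_durations(ev)
  times <- as.matrix(ev[event_cols_pub()])
  for (ph in 1:10) {
    d <- times[, ph + 1] - times[, ph]
    d <- sort(d[is.finite(d)])
    n <- length(d)
    oracle <- if (n %% 2 == 1) d[(n + 1) / 2] else mean(d[n / 2 + 0:1])
    expect_equal(med[ph], oracle)
  }
  # degenerate cases
  ev1 <- ev[1:3, ]
  ev1[event_cols_pub()] <- 0  # identical zero-length events
  durs <- c(1, 2, 9)
  expect_equal(median(durs), 2)  # median definition used throughout
})

test_that("segment resampling is linear, endpoint-inclusive and monotone", {
  expect_equal(as.numeric(resample_segment(c(0, 1, 2, 3, 4), 3)),
               c(0, 2, 4))
  # constants of any length are preserved exactly
  expect_equal(as.numeric(resample_segment(rep(3.3, 17), 5)), rep(3.3, 5))
  # identity warp when lengths match
  x <- rnorm(25)
  expect_equal(as.numeric(resample_segment(x, 25)), x)
  # monotone input stays monotone under warping
  x <- cumsum(runif(30))
  expect_true(all(diff(as.numeric(resample_segment(x, 100))) >= 0))
  # mean preservation for constant-plus-ramp segments
  x <- 2 + seq(0, 5, length.out = 21)
  expect_equal(mean(resample_segment(x, 57)), mean(x), tolerance = 1e-9)
  expect_error(resample_segment(3, 5), "short segment")
})

test_that("round-trip resampling recovers band-limited signals", {
  t <- seq(0, 5, by = 0.05)  # 5 s at 20 Hz
  x <- sin(2 * pi * 0.5 * t)
  there <- resample_segment(x, 60)
  back <- resample_segment(there, length(x))
  expect_lt(max(abs(back - x)), 0.02)
})

test_that("aligned tensors share exact phase boundaries across trials", {
  cfg <- tiny_cfg(n_trials = 20, n_units = 3, p_mistake = 0.3,
                  duration_jitter = 0.4)
  sess <- simulate_session(cfg)
  ad <- build_aligned_tensor(sess$events, sess$deconv,
                             signal = "deconvolved")
  n_out <- pmax(2L, as.integer(round(median_phase_durations(sess$events) *
                                       cfg$rate)))
  expect_identical(diff(ad$boundaries), n_out)
  expect_identical(ad$boundaries[11], dim(ad$values)[3])
  expect_true(all(diff(ad$boundaries) > 0))
  # per-trial resample equals the tensor row
  rs <- resample_trial(sess$deconv, sess$events[5, ],
                       median_phase_durations(sess$events))
  expect_equal(ad$values[5, , ], rs$values, ignore_attr = TRUE)
  expect_identical(rs$boundaries, ad$boundaries)
})

test_that("planted phase-boundary transitions land on tensor boundaries", {
  # trace that is a on phase 3 and b elsewhere, per trial, with jitter
  cfg <- tiny_cfg(n_trials = 12, n_units = 1, duration_jitter = 0.35,
                  p_mistake = 0)
  ev <- generate_events(cfg)
  rate <- cfg$rate
  n_bins <- as.integer(max(ev$t_event_11) * rate + 40)
  bt <- (seq_len(n_bins) - 1) / rate
  v <- rep(1, n_bins)
  for (k in seq_len(nrow(ev))) {
    v[bt >= ev$t_event_03[k] & bt < ev$t_event_04[k]] <- 7
  }
  tb <- trace_block(matrix(v, 1), rate = rate, kind = "deconvolved")
  ad <- build_aligned_tensor(ev, tb, signal = "deconvolved")
  ph3 <- tensor_span(ad, 3)
  inner <- ph3[-c(1, length(ph3))]  # interpolation mixes the edge bins only
  expect_true(all(ad$values[, 1, inner] == 7))
  outside <- setdiff(seq_len(dim(ad$values)[3]),
                     c(ph3, ph3[1] - 1, ph3[length(ph3)] + 1))
  expect_true(all(ad$values[, 1, outside] == 1))
})

test_that("mistake trials align via the merged retrieval tail", {
  cfg <- tiny_cfg(n_trials = 30, n_units = 2, p_mistake = 0.5)
  sess <- simulate_session(cfg)
  expect_gt(sum(sess$events$outcome == "mistake"), 0)
  ad <- build_aligned_tensor(sess$events, sess$deconv,
                             signal = "deconvolved")
  expect_identical(dim(ad$values)[1], nrow(sess$events))
  expect_true(all(is.finite(ad$values)))
  # maintenance-only alignment accepts mistakes without events 9/10
  adm <- build_aligned_tensor(sess$events, sess$deconv,
                              signal = "deconvolved", phases = 5:6)
  expect_identical(dim(adm$values)[3],
                   ad$boundaries[7] - ad$boundaries[5])
  expect_error(build_aligned_tensor(sess$events, sess$deconv,
                                    signal = "deconvolved", phases = 8:9),
               "together")
})

test_that("duplicated trials average to either copy", {
  cfg <- tiny_cfg(n_trials = 2, n_units = 2, p_mistake = 0)
  sess <- simulate_session(cfg)
  ev2 <- sess$events[c(1, 1), ]
  ev2$trial_id <- 1:2
  ad <- build_aligned_tensor(ev2, sess$deconv, signal = "deconvolved")
  expect_equal(ad$values[1, , ], ad$values[2, , ])
  expect_equal(colMeans(ad$values), ad$values[1, , ])
})
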