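test_that("generated event tables obey the trial grammar", {
  cfg <- tiny_cfg(n_trials = 60, p_mistake = 0.3)
  ev <- generate_events(cfg)
  expect_equal(nrow(ev), 60L)
  expect_identical(nrow(validate_events(ev)), 0L)
  times <- as.matrix(ev[event_cols()])
  for (k in seq_len(nrow(ev))) {
    present <- times[k, is.finite(times[k, ])]
    expect_true(all(diff(present) > 0))
    expect_length(present,
                  if (ev$outcome[k] == "mistake") 9L else 11L)
  }
  # mistake trials lack exactly events 9 and 10
  mist <- times[ev$outcome == "mistake", , drop = FALSE]
  expect_true(all(is.na(mist[, 9:10])))
  expect_true(all(is.finite(mist[, c(1:8, 11)])))
})

test_that("sample sides are pseudo-randomized with run length <= 3", {
  for (seed in c(1, 99, 2024)) {
    ev <- generate_events(tiny_cfg(n_trials = 200, seed = seed))
    runs <- rle(ev$side)$lengths
    expect_lte(max(runs), 3L)  # brute-force scan over the generated sides
  }
})

test_that("event generation is deterministic and degenerates correctly", {
  cfg <- tiny_cfg(n_trials = 25)
  expect_identical(generate_events(cfg), generate_events(cfg))
  # zero jitter: every trial's phase durations equal the medians
  cfg0 <- tiny_cfg(n_trials = 10, duration_jitter = 0, p_mistake = 0)
  ev <- generate_events(cfg0)
  times <- as.matrix(ev[event_cols()])
  durs <- times[, -1] - times[, -11]
  expect_equal(durs,
               matrix(rep(cfg0$median_phase_durations, each = 10), 10),
               ignore_attr = TRUE)
  # p_mistake = 0: all trials carry all 11 events
  expect_true(all(is.finite(times)))
})

test_that("generated phase-duration medians match the configured medians", {
  cfg <- tiny_cfg(n_trials = 250, duration_jitter = 0.3, p_mistake = 0)
  ev <- generate_events(cfg)
  times <- as.matrix(ev[event_cols()])
  med <- apply(times[, -1] - times[, -11], 2, median)
  expect_true(all(abs(med / cfg$median_phase_durations - 1) < 0.05))
})

test_that("a single noiseless spike produces an exponential transient at its bin", {
  cfg <- tiny_cfg(n_trials = 6, n_units = 1, snr = Inf,
                  background_rate = 0.05, fractions = c(E = 0, M = 0, R = 0),
                  p_mistake = 0)
  sess <- simulate_session(cfg)
  sp <- sess$truth$spikes
  expect_gt(nrow(sp), 0L)
  v <- sess$traces$values[1, ] - 1  # remove resting baseline
  onset <- which(v > 1e-9)[1]
  first_bin <- min(floor(sp$t * cfg$rate) + 1)
  expect_identical(onset, as.integer(first_bin))
  # beyond the last spike the decay is exponential with the kernel constant
  last_bin <- max(floor(sp$t * cfg$rate) + 1)
  decay <- exp(-1 / (cfg$kinetics_tau * cfg$rate))
  seg <- v[(last_bin + 1):(last_bin + 20)]
  expect_equal(seg[-1] / seg[-length(seg)], rep(decay, 19), tolerance = 1e-9)
})

test_that("maintenance units tile the delay in planted rank order", {
  cfg <- tiny_cfg(n_trials = 40, n_units = 10, snr = Inf,
                  fractions = c(E = 0, M = 1, R = 0), p_mistake = 0,
                  duration_jitter = 0, background_rate = 0)
  sess <- simulate_session(cfg)
  rank_gt <- sess$truth$planted_sequence_rank
  expect_setequal(rank_gt, 1:10)  # a permutation over maintenance units
  # argmax oracle on the noiseless trial-averaged deconvolved maintenance span
  ad <- build_aligned_tensor(sess$events, sess$deconv,
                             signal = "deconvolved", phases = 5:6)
  m <- colMeans(ad$values)
  peaks <- apply(m, 1, which.max)
  expect_gte(cor(peaks, rank_gt, method = "spearman"), 0.99)
  # spikes fall within trial bounds
  sp <- sess$truth$spikes
  ev <- as.matrix(sess$events[event_cols()])
  expect_true(all(sp$t >= ev[sp$trial, 1] & sp$t <= ev[sp$trial, 11]))
})

test_that("untuned units show no period preference beyond chance", {
  # repeated-simulation calibration: rank-sum p for a fixed period across
  # untuned sessions is approximately uniform
  p_m <- numeric(0)
  for (s in 1:20) {
    cfg <- tiny_cfg(n_trials = 30, n_units = 6, seed = 400 + s,
                    fractions = c(E = 0, M = 0, R = 0))
    sess <- simulate_session(cfg)
    m <- window_mean_activity(sess$events, sess$deconv, windows = "periods")
    st <- phase_significance(m)
    p_m <- c(p_m, st$p[, "M"])
  }
  expect_gt(suppressWarnings(ks.test(p_m, "punif")$p.value), 0.001)
})

test_that("bulk_from_cells sums unit activity per timepoint", {
  tb1 <- trace_block(matrix(2.5, 1, 6), rate = 20)
  expect_equal(bulk_from_cells(tb1)$values, tb1$values)
  tb2 <- trace_block(rbind(rep(1, 5), rep(2, 5)), rate = 20)
  expect_equal(as.numeric(bulk_from_cells(tb2)$values), rep(3, 5))
  set.seed(8)
  v <- matrix(rnorm(50), 5, 10)
  tb5 <- trace_block(v, rate = 20)
  direct <- vapply(1:10, function(j) sum(v[, j]), numeric(1))
  expect_equal(as.numeric(bulk_from_cells(tb5)$values), direct)
  expect_identical(bulk_from_cells(tb5)$modality, "photometry")
  expect_error(bulk_from_cells(trace_block(v, rate = 20,
                                           modality = "photometry")),
               "cellular")
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(rate = 0), "rate")
  expect_error(session_config(median_phase_durations = rep(1, 9)),
               "10 positive")
  expect_error(session_config(fractions = c(E = 0.6, M = 0.6, R = 0.2)),
               "fractions")
  expect_error(session_config(p_mistake = 1.5), "p_mistake")
})
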