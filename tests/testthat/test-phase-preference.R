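test_that("window means integrate the deconvolved signal per span", {
  cfg <- tiny_cfg(n_trials = 8, n_units = 2, p_mistake = 0)
  sess <- simulate_session(cfg)
  # silent unit: all means 0; constant unit: all means c
  tb <- sess$deconv
  tb$values[1, ] <- 0
  tb$values[2, ] <- 0.7
  m <- window_mean_activity(sess$events, tb, windows = "phases")
  expect_true(all(m[1, , ] == 0))
  expect_true(all(abs(m[2, , ] - 0.7) < 1e-12))
  # a single kernel in phase 3 puts the phase-3 mean on top
  tb$values[1, ] <- 0
  ev <- sess$events
  for (k in seq_len(nrow(ev))) {
    mid <- (ev$t_event_03[k] + ev$t_event_04[k]) / 2
    tb$values[1, floor(mid * cfg$rate) + 1] <- 1
  }
  m <- window_mean_activity(ev, tb, windows = "phases")
  for (k in seq_len(nrow(ev))) {
    expect_identical(unname(which.max(m[1, , k])), 3L)
  }
  # direct integration oracle for one trial/window
  idx <- which((seq_len(ncol(tb$values)) - 1) / cfg$rate >= ev$t_event_03[1] &
                 (seq_len(ncol(tb$values)) - 1) / cfg$rate < ev$t_event_04[1])
  expect_equal(unname(m[1, 3, 1]), mean(tb$values[1, idx]))
})

test_that("rank-sum significance matches exact enumeration on tiny tables", {
  # 3 trials x 3 windows, distinct values: enumerate all rank assignments
  means <- array(c(5, 9, 7,   1, 2, 3,   4, 6, 8),
                 dim = c(1, 3, 3))
  means <- aperm(means, c(1, 3, 2))  # unit x window x trial
  dimnames(means) <- list(NULL, c("w1", "w2", "w3"), NULL)
  st <- phase_significance(means)
  for (w in 1:3) {
    x <- means[1, w, ]
    y <- as.vector(means[1, -w, ])
    expect_equal(unname(st$p[1, w]), oracle_ranksum_greater(x, y))
  }
  # a unit active only in window 2 prefers window 2
  means2 <- array(0, dim = c(1, 3, 4),
                  dimnames = list(NULL, c("w1", "w2", "w3"), NULL))
  means2[1, 2, ] <- 1
  st2 <- phase_significance(means2)
  expect_identical(st2$preferred_window[1], 2L)
  # all-tied input gives p = 1, not an error
  means3 <- array(1, dim = c(2, 3, 3))
  expect_true(all(phase_significance(means3)$p == 1))
})

test_that("binarization is inclusive at the threshold", {
  st <- structure(list(p = matrix(c(0.009, 0.011, 0.01, 1), 2, 2),
                       sig = -log10(matrix(c(0.009, 0.011, 0.01, 1), 2, 2)),
                       preferred_window = c(1L, 1L),
                       windows = c("a", "b")),
                  class = "phase_significance")
  b <- binarize(st, alpha = 0.01)
  expect_identical(as.vector(b), c(TRUE, FALSE, TRUE, FALSE))
  st$p[] <- 1
  expect_false(any(binarize(st)))
})

test_that("coactivity matrices count pairwise AND fractions", {
  # all significant everywhere
  b <- matrix(TRUE, 5, 3)
  expect_true(all(coactivity_matrix(b) == 1))
  # disjoint E-only / M-only sets have zero off-diagonal overlap
  b <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
             c(FALSE, TRUE, FALSE))
  cm <- coactivity_matrix(b)
  expect_equal(cm[1, 2], 0)
  expect_equal(diag(cm), c(2, 1, 0) / 3, ignore_attr = TRUE)
  # random binary map against the pairwise AND-count oracle
  set.seed(42)
  b <- matrix(runif(80) < 0.4, 20, 4)
  cm <- coactivity_matrix(b)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm[i, j], sum(b[, i] & b[, j]) / 20)
  }
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) >= apply(cm, 1, max) - 1e-12))
  expect_error(coactivity_matrix(b[0, , drop = FALSE]), "no units")
})

test_that("period preference uses exact pairwise binomial tests", {
  # equal counts: no enrichment
  p <- period_preference_test(c(E = 10, M = 10, R = 10), 30)
  expect_true(all(p == 1))
  # all units prefer M: exact binomial tail in closed form
  p <- period_preference_test(c(E = 0, M = 50, R = 0), 50)
  expect_lt(p[["E_vs_M"]], 1e-10)
  expect_equal(p[["E_vs_M"]], 2 * 0.5^50, tolerance = 1e-9)
  expect_error(period_preference_test(c(E = 1, M = 1, R = 1), 0), "positive")
})

test_that("fisher combination matches the chi-square oracle", {
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  x2 <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(x2, 11.98, tolerance = 1e-3)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(x2, df = 4, lower.tail = FALSE))
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("preference monotonicity: boosting a window never lowers its score", {
  set.seed(11)
  base <- array(rexp(5 * 3 * 20), dim = c(5, 3, 20),
                dimnames = list(NULL, c("E", "M", "R"), NULL))
  st0 <- phase_significance(base)
  for (boost in c(0.5, 1, 2)) {
    up <- base
    up[, 2, ] <- up[, 2, ] + boost
    st1 <- phase_significance(up)
    expect_true(all(st1$sig[, 2] >= st0$sig[, 2] - 1e-12))
  }
})

test_that("high-SNR planted sessions recover the planted period", {
  cfg <- tiny_cfg(n_trials = 60, n_units = 20, snr = Inf,
                  fractions = c(E = 0.2, M = 0.6, R = 0.2))
  sess <- simulate_session(cfg)
  m <- window_mean_activity(sess$events, sess$deconv, windows = "periods")
  st <- phase_significance(m)
  tuned <- sess$truth$unit_class != "untuned"
  got <- c("E", "M", "R")[st$preferred_window[tuned]]
  expect_gte(mean(got == sess$truth$unit_class[tuned]), 0.95)
})
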