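test_that("activity probability normalizes and flags silent signals", {
  expect_equal(activity_probability(c(0, 2, 0))$p, c(0, 1, 0))
  expect_equal(activity_probability(rep(1, 4))$p, rep(0.25, 4))
  set.seed(2)
  for (i in 1:10) {
    x <- rexp(20)
    p <- activity_probability(x)
    expect_true(p$valid)
    expect_equal(sum(p$p), 1, tolerance = 1e-12)
    expect_equal(p$p, x / sum(x))
  }
  silent <- activity_probability(rep(0, 5))
  expect_false(silent$valid)
  expect_true(all(is.na(silent$p)))
  expect_error(activity_probability(c(-1, 2)), "nonnegative")
})

test_that("center of mass follows its defining sum", {
  d <- rep(0, 10); d[7] <- 1
  expect_equal(center_of_mass(d), 7)
  expect_equal(center_of_mass(rep(1 / 9, 9)), 5)  # (N + 1) / 2
  expect_equal(center_of_mass(c(0.5, 0.5)), 1.5)
  expect_error(center_of_mass(c(0.5, 0.4)), "sum to 1")
})

test_that("pairwise order fractions count trials correctly", {
  mk <- function(mu) {
    structure(list(mu = mu, valid = matrix(TRUE, nrow(mu), ncol(mu)),
                   span = NULL), class = "trial_centers")
  }
  # i always before j
  ctr <- mk(cbind(rep(1, 5), rep(2, 5)))
  expect_equal(pairwise_fraction(ctr, 1, 2), 1)
  expect_equal(pairwise_fraction(ctr, 2, 1), 0)
  # 5-trial toy with ties excluded: mu_j = (2,2,2,0,0) vs mu_i = 1
  ctr <- mk(cbind(rep(1, 5), c(2, 2, 2, 0, 0)))
  expect_equal(pairwise_fraction(ctr, 1, 2), 3 / 5)
  # f_ij + f_ji = 1 for tie-free inputs
  set.seed(5)
  ctr <- mk(matrix(rnorm(40), 20, 2))
  expect_equal(pairwise_fraction(ctr, 1, 2) + pairwise_fraction(ctr, 2, 1),
               1)
})

test_that("BDO matrix matches the brute-force pair-counting oracle", {
  set.seed(7)
  mu <- matrix(runif(12 * 8), 12, 8)
  bm <- bdo_matrix(mu)
  expect_equal(bm$bdo, oracle_bdo(mu))
  # antisymmetry and bounds
  expect_equal(bm$bdo, -t(bm$bdo))
  expect_true(all(abs(bm$bdo) <= 1))
  expect_equal(diag(bm$bdo), rep(0, 8))
  # with invalid entries (silent unit-trials) the oracle still agrees
  valid <- matrix(runif(12 * 8) > 0.2, 12, 8)
  mu2 <- mu; mu2[!valid] <- NA
  ctr <- structure(list(mu = mu2, valid = valid, span = NULL),
                   class = "trial_centers")
  bm2 <- bdo_matrix(ctr)
  expect_equal(bm2$bdo, oracle_bdo(mu, valid))
  expect_false(any(is.nan(bm2$bdo)))
  expect_false(is.nan(bm2$abdo))
  expect_error(bdo_matrix(mu[, 1, drop = FALSE]), "2 units")
})

test_that("BDO analytic extremes hold", {
  # consistent full sequence: +1 on the upper triangle in planted order
  mu <- matrix(rep(1:6, each = 10), 10, 6)
  bm <- bdo_matrix(mu)
  expect_true(all(bm$bdo[upper.tri(bm$bdo)] == 1))
  expect_true(all(bm$bdo[lower.tri(bm$bdo)] == -1))
  expect_equal(bm$abdo, 1)
  # half/half order split: BDO = 0
  mu <- cbind(c(rep(1, 5), rep(2, 5)), c(rep(2, 5), rep(1, 5)))
  expect_equal(bdo_matrix(mu)$bdo[1, 2], 0)
})

test_that("ABDO averages absolute off-diagonal entries", {
  expect_equal(abdo(matrix(0, 3, 3)), 0)
  m <- matrix(c(0, 1, -1, -1, 0, 1, 1, -1, 0), 3, 3)
  expect_equal(abdo(m), 1)
  m <- matrix(c(0, 0.2, -0.6, -0.2, 0, 1, 0.6, -1, 0), 3, 3)
  expect_equal(abdo(m), 0.6)
})

test_that("BDO depends only on within-trial order of centers", {
  set.seed(8)
  mu <- matrix(rnorm(15 * 5), 15, 5)
  base <- bdo_matrix(mu)$bdo
  warped <- mu
  for (k in 1:15) warped[k, ] <- exp(2 * mu[k, ]) + k  # monotone per trial
  expect_equal(bdo_matrix(warped)$bdo, base)
})

test_that("the permutation test rejects planted sequences and is seeded", {
  cfg <- tiny_cfg(n_trials = 40, n_units = 10,
                  fractions = c(E = 0, M = 1, R = 0), p_mistake = 0)
  sess <- simulate_session(cfg)
  ad <- build_aligned_tensor(sess$events, sess$deconv,
                             signal = "deconvolved", phases = 5:6)
  ctr <- trial_center_matrix(ad, span = seq_len(dim(ad$values)[3]))
  pt <- abdo_permutation_test(ctr, n_perm = 1000, seed = 99)
  expect_lte(pt$perm_p, 0.01)
  pt2 <- abdo_permutation_test(ctr, n_perm = 1000, seed = 99)
  expect_identical(pt$perm_p, pt2$perm_p)
  expect_identical(pt$null, pt2$null)
  expect_gt(pt$abdo_obs, max(pt$null))
  expect_error(abdo_permutation_test(ctr, n_perm = 0), "n_perm")
})

test_that("trial centers use min baseline and flag silent unit-trials", {
  cfg <- tiny_cfg(n_trials = 10, n_units = 4, background_rate = 0.2)
  sess <- simulate_session(cfg)
  ad <- build_aligned_tensor(sess$events, sess$deconv,
                             signal = "deconvolved", phases = 5:6)
  ctr <- trial_center_matrix(ad, span = seq_len(dim(ad$values)[3]))
  expect_true(any(!ctr$valid))  # sparse activity leaves silent trials
  expect_true(all(is.na(ctr$mu[!ctr$valid])))
  ok <- which(ctr$valid, arr.ind = TRUE)
  span_len <- dim(ad$values)[3]
  expect_true(all(ctr$mu[ok] >= 1 & ctr$mu[ok] <= span_len))
  # direct check of one center against the defining equations
  k <- ok[1, 1]; u <- ok[1, 2]
  x <- ad$values[k, u, ]
  x <- x - min(x)
  expect_equal(ctr$mu[k, u], center_of_mass(x / sum(x)))
})
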