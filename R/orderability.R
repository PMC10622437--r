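#' Activity probability profile of one unit-trial signal
#'
#' Normalizes a baseline-subtracted nonnegative signal so it sums to one,
#' turning it into the probability of the unit being active in each time
#' bin.  An all-zero (silent) signal is flagged rather than raising an
#' error; downstream orderability statistics treat the unit as invalid for
#' that trial.
#'
#' @param x numeric vector, nonnegative after baseline subtraction.
#' @return a list with `p` (the normalized profile, or `NA`s when silent)
#'   and `valid` (logical).
#' @export
#' @examples
#' activity_probability(c(0, 2, 0))$p  # 0 1 0
activity_probability <- function(x) {
  if (any(x < 0)) stop("signal must be nonnegative after baseline subtraction")
  s <- sum(x)
  if (s == 0) return(list(p = rep(NA_real_, length(x)), valid = FALSE))
  list(p = x / s, valid = TRUE)
}

#' Center of mass of an activity probability profile
#'
#' \eqn{\mu(p) = \sum_{t=1}^{N} t\,p(t)} in 1-based bin units: the weighted
#' average time of the whole trace, more robust to trial-to-trial noise
#' than the single peak bin.
#'
#' @param p probability profile summing to 1.
#' @return the center of mass (bin units).
#' @export
#' @examples
#' center_of_mass(c(0.5, 0.5))  # 1.5
center_of_mass <- function(p) {
  if (anyNA(p) || abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  sum(seq_along(p) * p)
}

#' Per-trial activity centers of mass over an analysis span
#'
#' For every trial and unit, subtracts the per-unit per-trial baseline
#' (the minimum by default, or a percentile) from the deconvolved signal
#' over the span, normalizes it to an activity probability, and takes its
#' center of mass.  Units silent in a trial are marked invalid for that
#' trial only.
#'
#' @param tensor a deconvolved `aligned_tensor`.
#' @param span time-bin indices to analyze, or a phase set / period label
#'   for [tensor_span()] (default the maintenance period).
#' @param trials which trials to use (`"correct"` or `"all"`).
#' @param baseline `"min"` or `"percentile"`.
#' @param percentile baseline percentile when `baseline = "percentile"`.
#' @return a list of class `trial_centers` with `mu` (trials x units,
#'   bin units within the span, `NA` where invalid), `valid` (logical
#'   trials x units) and `span`.
#' @export
trial_center_matrix <- function(tensor, span = "M",
                                trials = c("correct", "all"),
                                baseline = c("min", "percentile"),
                                percentile = 0.1) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  trials <- match.arg(trials)
  baseline <- match.arg(baseline)
  if (!is.numeric(span)) span <- tensor_span(tensor, span)
  keep <- if (trials == "correct") {
    which(tensor$labels$outcome == "correct")
  } else seq_len(dim(tensor$values)[1L])
  n_units <- dim(tensor$values)[2L]
  mu <- matrix(NA_real_, length(keep), n_units)
  valid <- matrix(FALSE, length(keep), n_units)
  tgrid <- seq_along(span)
  for (a in seq_along(keep)) {
    x <- tensor$values[keep[a], , span, drop = TRUE]
    x <- matrix(x, nrow = n_units)
    b <- if (baseline == "min") {
      apply(x, 1L, min)
    } else {
      apply(x, 1L, stats::quantile, probs = percentile, names = FALSE)
    }
    x <- pmax(x - b, 0)
    s <- rowSums(x)
    ok <- s > 0
    mu[a, ok] <- (x[ok, , drop = FALSE] %*% tgrid) / s[ok]
    valid[a, ] <- ok
  }
  structure(list(mu = mu, valid = valid, span = span),
            class = "trial_centers")
}

#' Fraction of trials in which one unit's activity center follows another's
#'
#' \eqn{f_{ij}} is the fraction of trials in which unit `j`'s center of
#' mass comes later than unit `i`'s, counted over trials where both units
#' are valid; exactly tied centers are excluded from the trial count, so
#' \eqn{f_{ij} + f_{ji} = 1} whenever any untied co-valid trial exists.
#'
#' @param centers a [trial_center_matrix()] result.
#' @param i,j unit indices.
#' @return `f_ij`, or `NA` if the pair has no untied co-valid trial.
#' @export
pairwise_fraction <- function(centers, i, j) {
  stopifnot(inherits(centers, "trial_centers"))
  ok <- centers$valid[, i] & centers$valid[, j] &
    centers$mu[, i] != centers$mu[, j]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NA_real_)
  mean(centers$mu[ok, j] > centers$mu[ok, i])
}

# Directed later-than counts over trials for all unit pairs.
# Returns G[i, j] = #trials{valid i,j; untied; mu_j > mu_i} and
# W[i, j] = #trials{valid i,j; untied}.
bdo_counts <- function(mu, valid) {
  n <- ncol(mu)
  G <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ok <- valid & valid[, j] & !is.na(mu) & !is.na(mu[, j]) &
      (mu != mu[, j])
    ok[is.na(ok)] <- FALSE
    later <- ok & (mu[, j] > mu)
    G[, j] <- colSums(later)
    W[, j] <- colSums(ok)
  }
  list(G = G, W = W)
}

#' Binary Directed Orderability matrix
#'
#' For every ordered unit pair (i, j), \eqn{BDO_{ij} = 2 f_{ij} - 1}:
#' +1 when unit j consistently follows unit i across trials, -1 when it
#' consistently leads, 0 when no consistent order occurs.  The matrix is
#' antisymmetric with a zero diagonal.  Pairs with no untied co-valid
#' trial are unorderable (`NA`) and excluded from the ABDO summary.
#'
#' @param centers a [trial_center_matrix()] result (or a plain trials x
#'   units matrix of centers, all entries valid).
#' @return an object of class `bdo_matrix`: a list with `bdo` (units x
#'   units), `abdo` (mean absolute off-diagonal BDO), `order` (units
#'   sorted by row-mean BDO, earliest first) and `n_pairs_valid`.
#' @export
bdo_matrix <- function(centers) {
  centers <- as_trial_centers(centers)
  if (ncol(centers$mu) < 2L) stop("need at least 2 units")
  cnt <- bdo_counts(centers$mu, centers$valid)
  f <- ifelse(cnt$W > 0, cnt$G / pmax(cnt$W, 1L), NA_real_)
  bdo <- 2 * f - 1
  diag(bdo) <- 0
  off <- abs(bdo[upper.tri(bdo) | lower.tri(bdo)])
  row_mean <- rowMeans(bdo, na.rm = TRUE)
  structure(list(bdo = bdo, abdo = mean(off, na.rm = TRUE),
                 order = order(row_mean, decreasing = TRUE),
                 n_pairs_valid = sum(cnt$W[upper.tri(cnt$W)] > 0)),
            class = "bdo_matrix")
}

as_trial_centers <- function(x) {
  if (inherits(x, "trial_centers")) return(x)
  mu <- as.matrix(x)
  structure(list(mu = mu,
                 valid = matrix(TRUE, nrow(mu), ncol(mu)),
                 span = NULL),
            class = "trial_centers")
}

#' @export
print.bdo_matrix <- function(x, ...) {
  cat("<bdo_matrix>", nrow(x$bdo), "units; ABDO =",
      format(x$abdo, digits = 4), "\n")
  invisible(x)
}

#' Mean absolute off-diagonal BDO
#'
#' @param bdo a `bdo_matrix` object or a plain antisymmetric matrix.
#' @return the ABDO scalar (unorderable pairs excluded).
#' @export
abdo <- function(bdo) {
  m <- if (inherits(bdo, "bdo_matrix")) bdo$bdo else as.matrix(bdo)
  off <- m[row(m) != col(m)]
  mean(abs(off), na.rm = TRUE)
}

#' Permutation test of population orderability
#'
#' The null hypothesis is that unit identities carry no consistent
#' temporal order: each permutation shuffles the unit labels independently
#' within every trial (so every trial keeps its set of activity centers
#' but loses which unit produced which) and recomputes ABDO.  The p-value
#' uses the add-one estimator \eqn{(1 + \#\{null \ge obs\})/(1 + n_{perm})}.
#'
#' @param centers a [trial_center_matrix()] result or trials x units
#'   matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a list with `abdo_obs`, `perm_p`, `null` (the permuted ABDO
#'   values) and `n_perm`.
#' @export
abdo_permutation_test <- function(centers, n_perm = 1000L, seed = NULL) {
  centers <- as_trial_centers(centers)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  mu <- centers$mu
  valid <- centers$valid
  if (ncol(mu) < 2L || nrow(mu) < 2L) {
    stop("need at least 2 units and 2 trials")
  }
  abdo_of <- function(m, v) {
    cnt <- bdo_counts(m, v)
    w <- cnt$W[upper.tri(cnt$W)]
    g <- cnt$G[upper.tri(cnt$G)]
    f <- g[w > 0] / w[w > 0]
    mean(abs(2 * f - 1))
  }
  obs <- abdo_of(mu, valid)
  n <- ncol(mu)
  with_rng(seed, {
    null <- vapply(seq_len(n_perm), function(b) {
      mp <- mu; vp <- valid
      for (k in seq_len(nrow(mu))) {
        p <- sample.int(n)
        mp[k, ] <- mu[k, p]
        vp[k, ] <- valid[k, p]
      }
      abdo_of(mp, vp)
    }, numeric(1))
    list(abdo_obs = obs,
         perm_p = (1 + sum(null >= obs)) / (1 + n_perm),
         null = null, n_perm = n_perm)
  })
}
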