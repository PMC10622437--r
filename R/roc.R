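#' Area under the ROC curve for two samples
#'
#' The Mann-Whitney identity: the probability that a random member of `b`
#' exceeds a random member of `a`, with ties counted 1/2.  0.5 means the
#' two groups are indistinguishable, 1 perfect separation with `b` above
#' `a`.
#'
#' @param a,b numeric samples of the two groups.
#' @return the AUC, in [0, 1].
#' @export
#' @examples
#' roc_auc(c(1, 3), c(2, 4))  # 0.75
roc_auc <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  (sum(r[(na + 1L):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

# Centered moving average over the time axis (columns), with truncated
# windows at the edges.
moving_average <- function(values, window = 3L) {
  if (window <= 1L) return(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  half <- (window - 1L) %/% 2L
  n <- ncol(values)
  cs <- cbind(0, t(apply(values, 1L, cumsum)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(values))
}

#' Time-resolved ROC discrimination of two trial types
#'
#' For each of `n_rep` repetitions, draws `n_draw` trials per class (with
#' replacement when a class has fewer trials than that, as mistake trials
#' typically do), smooths each trial's population signal with a centered
#' `window`-bin moving average, and computes the per-bin AUC between the
#' two classes.  The same procedure on label-shuffled trials (a fresh
#' permutation per repetition, preserving class sizes) yields the null
#' trace.  [compare_to_shuffle()] turns the two sets of draws into
#' Benjamini-Yekutieli-corrected significance calls.
#'
#' @param tensor an `aligned_tensor`; unit activity is summed into a bulk
#'   signal if more than one unit is present.
#' @param labels a factor or character vector with one label per trial
#'   (exactly two classes); AUC is oriented as P(second class > first),
#'   classes in factor-level order.
#' @param span time-bin indices to analyze (default: all bins).
#' @param n_draw trials drawn per class and repetition.
#' @param n_rep number of repetitions.
#' @param window moving-average window in bins.
#' @param alpha significance level for the adjusted per-bin calls.
#' @param seed integer seed for the draws and shuffles.
#' @return an object of class `auc_trace`: a list with `t` (analyzed bin
#'   indices), `auc_mean`, `auc_sem`, `shuffle_mean`, `shuffle_sem`,
#'   `p_raw`, `p_adj`, `sig_mask`, and the per-repetition draw matrices
#'   `auc_draws` / `shuffle_draws` (n_rep x bins).
#' @export
time_resolved_auc <- function(tensor, labels, span = NULL, n_draw = 100L,
                              n_rep = 20L, window = 3L, alpha = 0.01,
                              seed = NULL) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("labels must contain exactly two classes")
  }
  labels <- droplevels(labels)
  if (is.null(span)) span <- seq_len(dim(tensor$values)[3L])
  # bulk signal: trials x bins, smoothed once per trial
  bulk <- if (dim(tensor$values)[2L] == 1L) {
    tensor$values[, 1L, span, drop = TRUE]
  } else {
    apply(tensor$values[, , span, drop = FALSE], c(1L, 3L), sum)
  }
  bulk <- matrix(bulk, nrow = dim(tensor$values)[1L])
  bulk <- moving_average(bulk, window)

  idx1 <- which(labels == levels(labels)[1L])
  idx2 <- which(labels == levels(labels)[2L])
  if (length(idx1) == 0L || length(idx2) == 0L) stop("empty class")
  n_bins <- length(span)

  draw_auc <- function(i1, i2) {
    d1 <- sample(i1, n_draw, replace = length(i1) < n_draw)
    d2 <- sample(i2, n_draw, replace = length(i2) < n_draw)
    vapply(seq_len(n_bins), function(b) {
      roc_auc(bulk[d1, b], bulk[d2, b])
    }, numeric(1))
  }
  with_rng(seed, {
    real <- matrix(0, n_rep, n_bins)
    shuf <- matrix(0, n_rep, n_bins)
    all_idx <- c(idx1, idx2)
    for (r in seq_len(n_rep)) {
      real[r, ] <- draw_auc(idx1, idx2)
      perm <- sample(all_idx)  # preserve class sizes, fresh per repetition
      shuf[r, ] <- draw_auc(perm[seq_along(idx1)],
                            perm[length(idx1) + seq_along(idx2)])
    }
    cmp <- compare_to_shuffle(real, shuf, alpha = alpha)
    structure(list(t = span,
                   auc_mean = colMeans(real),
                   auc_sem = apply(real, 2L, stats::sd) / sqrt(n_rep),
                   shuffle_mean = colMeans(shuf),
                   shuffle_sem = apply(shuf, 2L, stats::sd) / sqrt(n_rep),
                   p_raw = cmp$p_raw, p_adj = cmp$p_adj,
                   sig_mask = cmp$sig_mask,
                   auc_draws = real, shuffle_draws = shuf,
                   classes = levels(labels)),
              class = "auc_trace")
  })
}

#' @export
print.auc_trace <- function(x, ...) {
  cat("<auc_trace>", length(x$t), "bins; classes",
      paste(x$classes, collapse = " vs "), ";",
      sum(x$sig_mask), "significant bins\n")
  invisible(x)
}

#' Compare real and shuffled AUC draws bin by bin
#'
#' A two-sided Wilcoxon rank-sum test per time bin between the real and
#' label-shuffled AUC draws, followed by Benjamini-Yekutieli false
#' discovery rate correction across all analyzed bins (valid under the
#' arbitrary dependence that smoothing and overlapping draws induce).
#'
#' @param real,shuffle numeric matrices of AUC draws (repetitions x bins).
#' @param alpha significance level applied to the adjusted p-values.
#' @return a list with `p_raw`, `p_adj` and logical `sig_mask`.
#' @export
compare_to_shuffle <- function(real, shuffle, alpha = 0.01) {
  stopifnot(is.matrix(real), is.matrix(shuffle),
            ncol(real) == ncol(shuffle))
  if (nrow(real) < 2L || nrow(shuffle) < 2L) {
    stop("need at least 2 draws per bin")
  }
  p_raw <- vapply(seq_len(ncol(real)), function(b) {
    x <- real[, b]; y <- shuffle[, b]
    if (length(unique(c(x, y))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "BY")
  list(p_raw = p_raw, p_adj = p_adj, sig_mask = p_adj <= alpha)
}
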