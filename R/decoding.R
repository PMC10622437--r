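#' Condition-averaged population activity
#'
#' @param tensor an `aligned_tensor`.
#' @param labels one label per trial.
#' @param condition the label value to average over.
#' @return units x bins matrix of per-condition mean activity.
#' @export
condition_mean <- function(tensor, labels, condition) {
  stopifnot(inherits(tensor, "aligned_tensor"),
            length(labels) == dim(tensor$values)[1L])
  sel <- which(labels == condition)
  if (length(sel) == 0L) stop("condition has no trials")
  x <- tensor$values[sel, , , drop = FALSE]
  apply(x, c(2L, 3L), mean)
}

#' Per-bin L2 distance between two condition means
#'
#' The Euclidean norm, over units, of the difference between the two
#' condition-averaged population vectors at each time bin.
#'
#' @param mean_a,mean_b units x bins matrices of matching shape.
#' @return numeric vector of per-bin distances.
#' @export
l2_trace <- function(mean_a, mean_b) {
  if (!all(dim(mean_a) == dim(mean_b))) stop("shape mismatch")
  sqrt(colSums((mean_a - mean_b)^2))
}

#' Permutation test of transient population encoding
#'
#' Computes the per-bin L2 distance between the two conditions' mean
#' population vectors and compares it with a null in which condition
#' labels are shuffled across trials (class sizes preserved).  The per-bin
#' p-value uses the add-one estimator; no multiple-testing correction is
#' applied, as the trace of \eqn{-\log_{10}(p)} values is itself the
#' result.
#'
#' @param tensor an `aligned_tensor` (deconvolved population activity).
#' @param labels one label per trial; exactly two classes.
#' @param span bin indices or phase-set/period label (default: all bins
#'   of the tensor).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return an object of class `decoding_trace`: a list with `t` (bin
#'   indices), `l2`, `p`, `neg_log10_p` and `n_perm`.
#' @export
l2_permutation_test <- function(tensor, labels, span = NULL,
                                n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (is.null(span)) span <- seq_len(dim(tensor$values)[3L])
  if (is.character(span)) span <- tensor_span(tensor, span)
  x <- tensor$values[, , span, drop = FALSE]
  cls <- levels(labels)
  ia <- which(labels == cls[1L]); ib <- which(labels == cls[2L])
  if (length(ia) == 0L || length(ib) == 0L) stop("empty class")

  # flatten to trials x (units * bins) so group means are single colMeans
  n_units <- dim(x)[2L]
  n_bins <- length(span)
  xf <- matrix(x, nrow = dim(x)[1L])
  l2_for <- function(a_idx, b_idx) {
    d <- colMeans(xf[a_idx, , drop = FALSE]) -
      colMeans(xf[b_idx, , drop = FALSE])
    sqrt(colSums(matrix(d * d, nrow = n_units, ncol = n_bins)))
  }
  obs <- l2_for(ia, ib)
  all_idx <- c(ia, ib)
  with_rng(seed, {
    exceed <- integer(length(span))
    for (b in seq_len(n_perm)) {
      perm <- sample(all_idx)
      null_b <- l2_for(perm[seq_along(ia)],
                       perm[length(ia) + seq_along(ib)])
      exceed <- exceed + (null_b >= obs)
    }
    p <- (1 + exceed) / (1 + n_perm)
    structure(list(t = span, l2 = obs, p = p,
                   neg_log10_p = -log10(p), n_perm = n_perm,
                   classes = cls),
              class = "decoding_trace")
  })
}

#' @export
print.decoding_trace <- function(x, ...) {
  cat("<decoding_trace>", length(x$t), "bins; classes",
      paste(x$classes, collapse = " vs "), ";",
      sum(x$p <= 0.01), "bins at p <= 0.01\n")
  invisible(x)
}

#' Fraction of units predictive of a behavioral contrast per window
#'
#' For each unit and task window, a two-sided rank-sum test compares the
#' per-trial window means between the two classes; units with p below
#' `alpha` are counted as predictive.  The window-level significance of
#' that count comes from a binomial model in which each unit could
#' independently be significant with probability `alpha` under the null:
#' the reported window p is the exact upper binomial tail
#' \eqn{P(X \ge count)}.
#'
#' @param means units x windows x trials array from
#'   [window_mean_activity()] (use `trials = "all"` when the contrast
#'   involves mistake trials).
#' @param labels one label per trial of the `means` array; two classes.
#' @param alpha per-unit significance level and binomial null probability.
#' @return a `data.frame` with one row per window: `window`, `n_predictive`,
#'   `fraction` and `p_window`.
#' @export
predictive_unit_fraction <- function(means, labels, alpha = 0.01) {
  stopifnot(length(dim(means)) == 3L,
            length(labels) == dim(means)[3L])
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  ia <- labels == levels(labels)[1L]
  ib <- labels == levels(labels)[2L]
  if (sum(ia) < 2L || sum(ib) < 2L) stop("need >= 2 trials per class")
  n_units <- dim(means)[1L]
  n_win <- dim(means)[2L]
  counts <- integer(n_win)
  for (w in seq_len(n_win)) {
    for (u in seq_len(n_units)) {
      x <- means[u, w, ia]; y <- means[u, w, ib]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2L || length(y) < 2L) next
      if (length(unique(c(x, y))) == 1L) next
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      if (p <= alpha) counts[w] <- counts[w] + 1L
    }
  }
  p_window <- stats::pbinom(counts - 1L, n_units, alpha,
                            lower.tail = FALSE)
  data.frame(window = dimnames(means)[[2L]] %||% as.character(seq_len(n_win)),
             n_predictive = counts,
             fraction = counts / n_units,
             p_window = p_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
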