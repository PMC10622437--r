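#' Per-trial mean activity of every unit in every task window
#'
#' For each unit and trial, the mean of the deconvolved signal over the
#' original (non-resampled) time span of each window — either the 10 trial
#' phases or the 3 task periods.  Windows whose bounding events are absent
#' in a trial (retrieval sub-phases of mistake trials) are `NA`.
#'
#' @param events trial event table.
#' @param traces deconvolved `trace_block` for the session.
#' @param windows `"phases"` (10 windows) or `"periods"` (3 windows).
#' @param trials `"correct"` (default, as phase-preference statistics use
#'   correct trials only) or `"all"`.
#' @return numeric array units x windows x trials of mean activities, with
#'   dimnames on the window axis.
#' @export
window_mean_activity <- function(events, traces,
                                 windows = c("phases", "periods"),
                                 trials = c("correct", "all")) {
  windows <- match.arg(windows)
  trials <- match.arg(trials)
  stopifnot(inherits(traces, "trace_block"))
  if (traces$kind != "deconvolved") {
    stop("window_mean_activity() expects deconvolved traces")
  }
  if (trials == "correct") events <- events[events$outcome == "correct", ,
                                            drop = FALSE]
  ev <- as.matrix(events[event_cols()])
  win_bounds <- if (windows == "phases") {
    cbind(1:10, 2:11)
  } else {
    cbind(c(1L, 5L, 7L), c(5L, 7L, 11L))
  }
  win_names <- if (windows == "phases") {
    sprintf("phase_%02d", 1:10)
  } else c("E", "M", "R")
  n_units <- nrow(traces$values)
  out <- array(NA_real_, dim = c(n_units, nrow(win_bounds), nrow(ev)),
               dimnames = list(NULL, win_names, NULL))
  for (k in seq_len(nrow(ev))) {
    for (w in seq_len(nrow(win_bounds))) {
      t_a <- ev[k, win_bounds[w, 1L]]
      t_b <- ev[k, win_bounds[w, 2L]]
      if (!is.finite(t_a) || !is.finite(t_b)) next
      idx <- bin_range(t_a, t_b, traces$rate, traces$t0,
                       ncol(traces$values))
      if (length(idx) == 0L) next
      out[, w, k] <- rowMeans(traces$values[, idx, drop = FALSE])
    }
  }
  out
}

#' Rank-sum phase-preference significance of every unit
#'
#' For each unit and window, a one-sided Wilcoxon rank-sum test of that
#' window's per-trial mean activities against the pool of all other
#' windows' per-trial means (alternative: greater, i.e. preferentially
#' active there).  Significance is reported as \eqn{-\log_{10}(p)}; the
#' preferred window of a unit is the one with the largest value, ties
#' broken in favor of the earlier window.
#'
#' @param means units x windows x trials array from
#'   [window_mean_activity()].
#' @return an object of class `phase_significance`: a list with `p`
#'   (units x windows raw p-values), `sig` (\eqn{-\log_{10}(p)}),
#'   `preferred_window` (integer per unit) and `windows` (window names).
#' @export
phase_significance <- function(means) {
  stopifnot(length(dim(means)) == 3L)
  n_units <- dim(means)[1L]
  n_win <- dim(means)[2L]
  if (dim(means)[3L] < 2L) stop("need at least 2 trials")
  p <- matrix(1, n_units, n_win,
              dimnames = list(NULL, dimnames(means)[[2L]]))
  for (u in seq_len(n_units)) {
    for (w in seq_len(n_win)) {
      x <- means[u, w, ]
      y <- as.vector(means[u, -w, , drop = FALSE])
      x <- x[is.finite(x)]
      y <- y[is.finite(y)]
      if (length(x) == 0L || length(y) == 0L) next
      if (length(unique(c(x, y))) == 1L) next  # all tied: p = 1
      p[u, w] <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "greater")$p.value)
    }
  }
  sig <- -log10(p)
  structure(list(p = p, sig = sig,
                 preferred_window = unname(apply(sig, 1L, which.max)),
                 windows = colnames(p)),
            class = "phase_significance")
}

#' @export
print.phase_significance <- function(x, ...) {
  cat("<phase_significance>", nrow(x$p), "units x", ncol(x$p), "windows;",
      sum(x$p <= 0.01), "cells significant at p <= 0.01\n")
  invisible(x)
}

#' Binarize phase-preference significance at a threshold
#'
#' @param sig_table a [phase_significance()] result.
#' @param alpha significance threshold; the comparison is inclusive
#'   (`p <= alpha` is significant).
#' @return logical units x windows matrix.
#' @export
binarize <- function(sig_table, alpha = 0.01) {
  stopifnot(inherits(sig_table, "phase_significance"))
  sig_table$p <= alpha
}

#' Fraction of units co-active in pairs of task windows
#'
#' Entry (a, b) is the fraction of units significantly active in both
#' windows a and b; the diagonal is the fraction significant in each
#' single window, so the matrix is symmetric with row-dominant diagonal.
#'
#' @param binary logical units x windows matrix from [binarize()].
#' @return numeric windows x windows matrix of fractions in [0, 1].
#' @export
coactivity_matrix <- function(binary) {
  stopifnot(is.matrix(binary))
  if (nrow(binary) == 0L) stop("no units")
  crossprod(binary * 1) / nrow(binary)
}

#' Binomial test for period-preference enrichment
#'
#' Tests, for every pair of task periods, whether more units prefer one
#' period than the other.  Under the null hypothesis each unit is equally
#' likely to prefer any of the three periods, so conditional on preferring
#' one of a given pair, each member of the pair is equally likely: the
#' pairwise test is an exact two-sided binomial test with success
#' probability 1/2 on the counts restricted to the pair.
#'
#' @param counts named integer vector of units preferring each period
#'   (names `E`, `M`, `R`).
#' @param n_units total number of units; `sum(counts)` must not exceed it.
#' @return named numeric vector of two-sided p-values per period pair.
#' @export
#' @examples
#' period_preference_test(c(E = 10, M = 30, R = 10), 50)
period_preference_test <- function(counts, n_units) {
  if (n_units <= 0L) stop("n_units must be positive")
  stopifnot(all(c("E", "M", "R") %in% names(counts)),
            sum(counts) <= n_units)
  pairs <- utils::combn(c("E", "M", "R"), 2L)
  p <- apply(pairs, 2L, function(pr) {
    n_pair <- counts[pr[1L]] + counts[pr[2L]]
    if (n_pair == 0L) return(1)
    stats::binom.test(counts[pr[1L]], n_pair, p = 0.5)$p.value
  })
  names(p) <- apply(pairs, 2L, paste, collapse = "_vs_")
  p
}

#' Combine independent p-values with Fisher's method
#'
#' \eqn{X^2 = -2 \sum \ln p_i} is referred to a chi-square distribution
#' with \eqn{2k} degrees of freedom, the standard way of pooling per-mouse
#' p-values into one session-spanning significance statement.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))
fisher_combine <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  x2 <- -2 * sum(log(pvals))
  stats::pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Fractions of units preferring each window
#'
#' @param sig_table a [phase_significance()] result.
#' @return named numeric vector: the proportion of units whose preferred
#'   window is each window.
#' @export
preference_fractions <- function(sig_table) {
  stopifnot(inherits(sig_table, "phase_significance"))
  tab <- tabulate(sig_table$preferred_window, nbins = ncol(sig_table$p))
  stats::setNames(tab / nrow(sig_table$p), sig_table$windows)
}

#' Mean activity of units within their preferred window
#'
#' For each window, the mean (over units preferring it) of the across-trial
#' mean activity in that window — the per-period activity level that,
#' multiplied by the preferring fraction, estimates each period's
#' contribution to the bulk population signal.
#'
#' @param means units x windows x trials array from
#'   [window_mean_activity()].
#' @param sig_table a [phase_significance()] result on the same windows.
#' @return named numeric vector of mean activities per window (`NA` for
#'   windows no unit prefers).
#' @export
preferred_window_activity <- function(means, sig_table) {
  stopifnot(inherits(sig_table, "phase_significance"),
            dim(means)[2L] == ncol(sig_table$p))
  unit_mean <- apply(means, c(1L, 2L), mean, na.rm = TRUE)
  out <- rep(NA_real_, ncol(sig_table$p))
  for (w in seq_len(ncol(sig_table$p))) {
    sel <- sig_table$preferred_window == w
    if (any(sel)) out[w] <- mean(unit_mean[sel, w])
  }
  stats::setNames(out, sig_table$windows)
}

#' Ratio of bulk-signal contributions between two task periods
#'
#' The contribution of a period to the summed population signal is the
#' fraction of units preferring it times their mean activity there; the
#' ratio of two such products says how much more strongly one period
#' recruits the population than another (e.g. maintenance vs encoding).
#'
#' @param fractions named fractions of units preferring each period.
#' @param activities named mean activity of those units in their period.
#' @param num,den period labels for numerator and denominator.
#' @return the contribution ratio (a scalar).
#' @export
#' @examples
#' recruitment_activity_ratio(c(E = 0.22, M = 0.56, R = 0.22),
#'                            c(E = 0.18, M = 0.123, R = 0.176))
recruitment_activity_ratio <- function(fractions, activities,
                                       num = "M", den = "E") {
  stopifnot(num %in% names(fractions), den %in% names(fractions),
            num %in% names(activities), den %in% names(activities))
  unname((fractions[num] * activities[num]) /
           (fractions[den] * activities[den]))
}
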