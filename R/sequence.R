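#' Split correct trials into training and test halves
#'
#' Random disjoint halves of the correct trials; with an odd count the
#' training set receives the extra trial.
#'
#' @param trial_idx integer indices of the correct trials.
#' @param seed integer seed.
#' @return a list with integer vectors `train` and `test`.
#' @export
split_trials <- function(trial_idx, seed = NULL) {
  n <- length(trial_idx)
  if (n < 2L) stop("need at least 2 correct trials to split")
  with_rng(seed, {
    shuffled <- sample(trial_idx)
    n_train <- ceiling(n / 2)
    list(train = sort(shuffled[seq_len(n_train)]),
         test = sort(shuffled[(n_train + 1L):n]))
  })
}

#' Peak times of trial-averaged normalized signals
#'
#' Averages each unit's resampled signal over a set of trials within the
#' analysis span, normalizes the mean trace to a maximum of 1, and returns
#' the peak (argmax) time; ties resolve to the earliest bin.  Units whose
#' mean trace is identically zero are flagged and excluded from shift
#' statistics.
#'
#' @param tensor a deconvolved `aligned_tensor`.
#' @param trial_idx trials to average (indices into the tensor).
#' @param span bin indices or a phase-set/period label (default
#'   maintenance).
#' @return a list with `peak_bin` (1-based bin within the span),
#'   `peak_time` (seconds from span start), `valid` (logical per unit)
#'   and `mean_signal` (units x span matrix, max-normalized).
#' @export
peak_times <- function(tensor, trial_idx, span = "M") {
  stopifnot(inherits(tensor, "aligned_tensor"), length(trial_idx) >= 1L)
  if (!is.numeric(span)) span <- tensor_span(tensor, span)
  x <- tensor$values[trial_idx, , span, drop = FALSE]
  m <- colMeans(x)  # averages over trials, leaving units x span
  peak_max <- apply(m, 1L, max)
  valid <- peak_max > 0
  norm <- m / ifelse(peak_max > 0, peak_max, 1)
  peak_bin <- apply(m, 1L, which.max)  # which.max: earliest on ties
  peak_bin[!valid] <- NA_integer_
  list(peak_bin = peak_bin,
       peak_time = (peak_bin - 1L) / tensor$rate,
       valid = valid, mean_signal = norm)
}

#' Peak-shift statistics between two orderings of the same units
#'
#' Per-unit absolute peak-time differences in seconds, with their median
#' and 75th percentile (linear interpolation between order statistics).
#'
#' @param peaks_train,peaks_other [peak_times()] results on matched units.
#' @return a list with `shift` (seconds per unit, `NA` where either peak
#'   is invalid), `median`, `p75` and `n`.
#' @export
shift_statistics <- function(peaks_train, peaks_other) {
  if (length(peaks_train$peak_time) != length(peaks_other$peak_time)) {
    stop("unit sets must match")
  }
  ok <- peaks_train$valid & peaks_other$valid
  if (!any(ok)) stop("no unit has a valid peak in both conditions")
  shift <- rep(NA_real_, length(ok))
  shift[ok] <- abs(peaks_other$peak_time[ok] - peaks_train$peak_time[ok])
  list(shift = shift,
       median = stats::median(shift[ok]),
       p75 = unname(stats::quantile(shift[ok], 0.75)),
       n = sum(ok))
}

#' Compare two paired peak-shift distributions
#'
#' Two-sided Wilcoxon signed-rank test on the per-unit paired differences
#' (zero differences dropped, the standard convention).  Returns p = 1
#' when every difference is zero.
#'
#' @param shift_a,shift_b per-unit shifts (seconds), paired by unit.
#' @return the two-sided p-value.
#' @export
compare_shift_distributions <- function(shift_a, shift_b) {
  if (length(shift_a) != length(shift_b)) stop("shifts must be paired")
  ok <- is.finite(shift_a) & is.finite(shift_b)
  d <- shift_a[ok] - shift_b[ok]
  if (length(d) == 0L) stop("no overlapping units")
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(shift_a[ok], shift_b[ok],
                                      paired = TRUE)$p.value)
}

#' Train/test validation of delay-period neuronal sequences
#'
#' Splits the correct trials into a training and a test half, orders units
#' by the peak times of their trial-averaged maintenance signals in the
#' training set, and measures how far response peaks shift on the held-out
#' test trials and on mistake trials.  An intact sequence keeps test-set
#' peaks close to their training positions; a degraded (mistake) sequence
#' shifts them further, which the paired signed-rank comparison of the two
#' shift distributions quantifies.
#'
#' @param tensor a deconvolved `aligned_tensor` containing both correct
#'   and mistake trials.
#' @param span analysis span (default maintenance).
#' @param units optional unit subset to analyze.
#' @param seed integer seed for the trial split.
#' @return an object of class `sequence_result`: a list with `order`
#'   (units sorted by training peak), per-condition [peak_times()]
#'   results, `shift_test`, `shift_mistake` ([shift_statistics()] lists)
#'   and `p_compare` (paired two-sided signed-rank p, `NA` when the
#'   session has no mistake trials).
#' @export
sequence_analysis <- function(tensor, span = "M", units = NULL,
                              seed = NULL) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  if (!is.numeric(span)) span <- tensor_span(tensor, span)
  if (is.null(units)) units <- seq_len(dim(tensor$values)[2L])
  correct <- which(tensor$labels$outcome == "correct")
  mistake <- which(tensor$labels$outcome == "mistake")
  halves <- split_trials(correct, seed = seed)

  sub <- function(trials) {
    tens <- tensor
    tens$values <- tensor$values[, units, , drop = FALSE]
    peak_times(tens, trials, span = span)
  }
  pk_train <- sub(halves$train)
  pk_test <- sub(halves$test)
  shift_test <- shift_statistics(pk_train, pk_test)
  pk_mist <- NULL
  shift_mist <- NULL
  p_cmp <- NA_real_
  if (length(mistake) >= 1L) {
    pk_mist <- sub(mistake)
    shift_mist <- shift_statistics(pk_train, pk_mist)
    p_cmp <- compare_shift_distributions(shift_test$shift,
                                         shift_mist$shift)
  }
  structure(list(order = order(pk_train$peak_time),
                 split = halves,
                 peak_train = pk_train, peak_test = pk_test,
                 peak_mistake = pk_mist,
                 shift_test = shift_test, shift_mistake = shift_mist,
                 p_compare = p_cmp, units = units, span = span),
            class = "sequence_result")
}

#' @export
print.sequence_result <- function(x, ...) {
  cat("<sequence_result>", length(x$units), "units;",
      "median test shift", format(x$shift_test$median, digits = 3), "s")
  if (!is.null(x$shift_mistake)) {
    cat("; median mistake shift",
        format(x$shift_mistake$median, digits = 3), "s; p =",
        format(x$p_compare, digits = 3))
  }
  cat("\n")
  invisible(x)
}
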