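#' Per-trial baseline statistics of a trace block
#'
#' The baseline window is the `window` seconds immediately before the start
#' of the maintenance period (event 5).  `F0` is the per-unit mean and
#' `sigma` the per-unit sample standard deviation of the fluorescence in
#' that window; both feed the per-trial \eqn{\Delta F/F} and z-score
#' transforms.
#'
#' @param trace a session-long `trace_block`.
#' @param events_row one row of a trial event table.
#' @param window baseline window length in seconds (default 1 s).
#' @return a list with `F0`, `sigma` (numeric per unit) and `window`.
#' @export
trial_baseline <- function(trace, events_row, window = 1) {
  stopifnot(inherits(trace, "trace_block"), window > 0)
  t5 <- events_row$t_event_05
  idx <- bin_range(t5 - window, t5, trace$rate, trace$t0,
                   ncol(trace$values))
  if (length(idx) < 2L) {
    stop("degenerate baseline: window before event 5 not inside recording")
  }
  v <- trace$values[, idx, drop = FALSE]
  list(F0 = rowMeans(v), sigma = apply(v, 1L, stats::sd), window = window)
}

#' Express a trial's fluorescence as percentage change from baseline
#'
#' Computes \eqn{\Delta F/F = (F(t) - F_0) / F_0 \times 100\%} over the trial
#' segment from event 1 to event 11, with \eqn{F_0} the mean fluorescence in
#' the baseline window before event 5.
#'
#' @inheritParams trial_baseline
#' @param baseline_window baseline window length in seconds.
#' @return a `trace_block` of kind `"dff"` covering the trial segment.
#' @export
compute_dff <- function(trace, events_row, baseline_window = 1) {
  b <- trial_baseline(trace, events_row, baseline_window)
  if (any(b$F0 == 0)) stop("degenerate baseline: F0 = 0")
  seg <- trial_segment(trace, events_row)
  v <- (seg$values - b$F0) / b$F0 * 100
  trace_block(v, rate = trace$rate, t0 = seg$t0,
              modality = trace$modality, kind = "dff")
}

#' Z-score a trial's fluorescence against its baseline statistics
#'
#' Computes \eqn{(F(t) - F_0)/\sigma} over the trial segment, with
#' \eqn{F_0} and \eqn{\sigma} the mean and sample standard deviation of the
#' fluorescence in the baseline window before event 5.
#'
#' @inheritParams trial_baseline
#' @param baseline optional precomputed [trial_baseline()]; computed from
#'   `events_row` when missing.
#' @return a `trace_block` of kind `"zscore"` covering the trial segment.
#' @export
zscore_trial <- function(trace, events_row, baseline = NULL) {
  if (is.null(baseline)) baseline <- trial_baseline(trace, events_row)
  if (any(baseline$sigma <= 0)) {
    stop("constant baseline: sigma = 0, cannot z-score")
  }
  seg <- trial_segment(trace, events_row)
  v <- (seg$values - baseline$F0) / baseline$sigma
  trace_block(v, rate = trace$rate, t0 = seg$t0,
              modality = trace$modality, kind = "zscore")
}

# Extract the bins of the trial segment [event 1, event 11).
trial_segment <- function(trace, events_row) {
  idx <- bin_range(events_row$t_event_01, events_row$t_event_11,
                   trace$rate, trace$t0, ncol(trace$values))
  if (length(idx) < 2L) stop("trial segment outside recording")
  list(values = trace$values[, idx, drop = FALSE],
       t0 = bin_to_time(idx[1L], trace$rate, trace$t0), idx = idx)
}

#' Median phase durations across the trials of a session
#'
#' For each of the 10 trial phases, the median across all trials in which
#' both bounding events are present (mistake trials lack events 9 and 10,
#' so they do not contribute to the retrieval sub-phases 8-10).  These
#' medians define the common timebase that every trial is resampled onto.
#'
#' @param events a trial event table.
#' @return numeric vector of 10 median durations (seconds).
#' @export
median_phase_durations <- function(events) {
  ev <- as.matrix(events[event_cols()])
  durs <- ev[, -1L, drop = FALSE] - ev[, -wm_n_events(), drop = FALSE]
  out <- apply(durs, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(out))) {
    stop("missing phase: no trial has events bounding phase(s) ",
         paste(which(!is.finite(out)), collapse = ", "))
  }
  unname(out)
}

#' Linearly resample a segment onto a fixed number of bins
#'
#' Piecewise-linear interpolation on an endpoints-inclusive grid: the first
#' and last output samples coincide with the first and last input samples,
#' so constants are preserved exactly and the warp is monotone.
#'
#' @param values numeric matrix (units x samples) or vector.
#' @param n_out number of output samples (>= 2).
#' @return matrix (units x `n_out`).
#' @export
#' @examples
#' resample_segment(c(0, 1, 2, 3, 4), 3)  # 0 2 4
resample_segment <- function(values, n_out) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  n_in <- ncol(values)
  if (n_in < 2L) stop("short segment: fewer than 2 samples")
  if (n_out < 2L) stop("n_out must be >= 2")
  pos <- 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  lo <- pmin(floor(pos), n_in - 1L)
  w <- pos - lo
  values[, lo, drop = FALSE] * rep(1 - w, each = nrow(values)) +
    values[, lo + 1L, drop = FALSE] * rep(w, each = nrow(values))
}

# Output bin count per phase: round(target duration x rate), at least 2.
phase_bin_counts <- function(targets, rate) {
  pmax(2L, as.integer(round(targets * rate)))
}

#' Resample one trial onto the common phase timebase
#'
#' Each requested phase segment is independently interpolated onto
#' `round(target x rate)` bins (minimum 2), so phase boundaries land on the
#' same bin index in every trial.  For mistake trials, which lack events 9
#' and 10, the retrieval tail from event 8 to event 11 is resampled as one
#' segment onto the combined bin count of phases 8-10.
#'
#' @param trace a session-long `trace_block`.
#' @param events_row one row of a trial event table.
#' @param targets the 10 target (median) phase durations in seconds.
#' @param phases integer phase indices to include (increasing subset of
#'   1..10; if any of phases 8-10 is requested, all three must be).
#' @param transform optional function applied to the trial's values matrix
#'   (units x bins of the whole recording) before resampling, e.g. a
#'   baseline z-score.
#' @return a list with `values` (units x T matrix) and `boundaries`
#'   (integer vector, one per requested phase plus one; phase j occupies
#'   bins `(boundaries[j]+1):boundaries[j+1]`).
#' @export
resample_trial <- function(trace, events_row, targets, phases = 1:10,
                           transform = NULL) {
  stopifnot(inherits(trace, "trace_block"),
            length(targets) == wm_n_phases(), all(targets > 0),
            all(diff(phases) > 0), all(phases %in% 1:10))
  tail_ph <- intersect(phases, 8:10)
  if (length(tail_ph) > 0L && length(tail_ph) < 3L) {
    stop("phases 8-10 must be requested together or not at all")
  }
  rate <- trace$rate
  n_out <- phase_bin_counts(targets, rate)
  vals <- trace$values
  if (!is.null(transform)) vals <- transform(vals)
  ev <- as.numeric(events_row[1L, event_cols()])
  mistake <- identical(events_row$outcome, "mistake")

  seg_for <- function(t_a, t_b, m) {
    idx <- bin_range(t_a, t_b, rate, trace$t0, ncol(vals))
    if (length(idx) < 2L) {
      stop("short segment: phase spans fewer than 2 samples")
    }
    resample_segment(vals[, idx, drop = FALSE], m)
  }
  pieces <- list()
  j <- 1L
  while (j <= length(phases)) {
    ph <- phases[j]
    if (mistake && ph == 8L) {
      pieces[[length(pieces) + 1L]] <- seg_for(ev[8L], ev[11L],
                                               sum(n_out[8:10]))
      j <- j + 3L
    } else {
      pieces[[length(pieces) + 1L]] <- seg_for(ev[ph], ev[ph + 1L],
                                               n_out[ph])
      j <- j + 1L
    }
  }
  list(values = do.call(cbind, pieces),
       boundaries = cumsum(c(0L, n_out[phases])))
}

#' Build the trial-aligned tensor of a session
#'
#' Applies the per-trial signal transform (z-score or \eqn{\Delta F/F}
#' against the pre-maintenance baseline; none for deconvolved or raw
#' signals), resamples every trial segment-wise onto the common median-
#' duration timebase, and stacks the results into a trials x units x time
#' array with shared phase-boundary indices.
#'
#' @param events trial event table.
#' @param trace session-long `trace_block` (fluorescence for
#'   `signal = "zscore"`/`"dff"`, deconvolved activity for
#'   `signal = "deconvolved"`).
#' @param signal which signal kind to align.
#' @param targets median phase durations; computed from `events` when NULL.
#' @param phases phase subset to align (see [resample_trial()]).
#' @param baseline_window baseline window (seconds) for z-score / dff.
#' @return an object of class `aligned_tensor`: a list with `values`
#'   (trials x units x T array), `boundaries`, `phases`,
#'   `median_durations`, `rate`, `signal` and `labels` (a `data.frame`
#'   with `trial_id`, `side`, `outcome`).
#' @export
build_aligned_tensor <- function(events, trace,
                                 signal = c("zscore", "dff", "deconvolved",
                                            "raw"),
                                 targets = NULL, phases = 1:10,
                                 baseline_window = 1) {
  signal <- match.arg(signal)
  if (signal == "deconvolved" && trace$kind != "deconvolved") {
    stop("signal = 'deconvolved' requires a deconvolved trace_block")
  }
  if (is.null(targets)) targets <- median_phase_durations(events)
  n_trials <- nrow(events)
  boundaries <- NULL
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    row_k <- events[k, , drop = FALSE]
    transform <- switch(signal,
      zscore = {
        b <- trial_baseline(trace, row_k, baseline_window)
        if (any(b$sigma <= 0)) stop("constant baseline in trial ", k)
        function(v) (v - b$F0) / b$sigma
      },
      dff = {
        b <- trial_baseline(trace, row_k, baseline_window)
        if (any(b$F0 == 0)) stop("zero baseline F0 in trial ", k)
        function(v) (v - b$F0) / b$F0 * 100
      },
      NULL)
    rs <- resample_trial(trace, row_k, targets, phases = phases,
                         transform = transform)
    boundaries <- rs$boundaries
    rows[[k]] <- rs$values
  }
  values <- array(0, dim = c(n_trials, nrow(trace$values),
                             boundaries[length(boundaries)]))
  for (k in seq_len(n_trials)) values[k, , ] <- rows[[k]]
  structure(list(values = values, boundaries = boundaries, phases = phases,
                 median_durations = targets, rate = trace$rate,
                 signal = signal,
                 labels = events[, c("trial_id", "side", "outcome")]),
            class = "aligned_tensor")
}

#' @export
print.aligned_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<aligned_tensor>", d[1L], "trials x", d[2L], "units x", d[3L],
      "bins;", x$signal, "signal; phases",
      paste(range(x$phases), collapse = "-"), "\n")
  invisible(x)
}

#' Bin indices of a phase span on the aligned timebase
#'
#' @param tensor an `aligned_tensor`.
#' @param phases phase indices (must be part of the tensor) or a period
#'   label `"E"`, `"M"`, `"R"`.
#' @return integer vector of time-bin indices covering those phases.
#' @export
tensor_span <- function(tensor, phases = "M") {
  if (is.character(phases)) phases <- wm_periods()[[match.arg(phases,
                                                   c("E", "M", "R"))]]
  pos <- match(phases, tensor$phases)
  if (anyNA(pos)) stop("phase(s) not present in tensor")
  unlist(lapply(pos, function(j) {
    (tensor$boundaries[j] + 1L):tensor$boundaries[j + 1L]
  }))
}
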