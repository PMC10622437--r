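#' Container for a block of activity traces
#'
#' A `trace_block` holds a units x timepoints matrix of activity sampled at
#' a fixed rate, together with the acquisition metadata the pipeline needs:
#' the sampling rate, the time of the first sample, the recording modality
#' (`"photometry"` for bulk signals, `"cellular"` for single-cell traces)
#' and the signal kind (`"raw"` fluorescence, `"dff"`, `"zscore"`, or
#' `"deconvolved"` spike-rate-like activity).
#'
#' @param values numeric matrix, units x timepoints.
#' @param rate sampling rate in Hz.
#' @param t0 time (seconds) of the first sample.
#' @param modality `"photometry"` or `"cellular"`.
#' @param kind `"raw"`, `"dff"`, `"zscore"` or `"deconvolved"`.
#' @return an object of class `trace_block`.
#' @export
#' @examples
#' tb <- trace_block(matrix(rnorm(40), nrow = 2), rate = 20)
#' dim(tb$values)
trace_block <- function(values, rate, t0 = 0,
                        modality = c("cellular", "photometry"),
                        kind = c("raw", "dff", "zscore", "deconvolved")) {
  modality <- match.arg(modality)
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(values = values, rate = rate, t0 = t0,
                 modality = modality, kind = kind),
            class = "trace_block")
}

#' @export
print.trace_block <- function(x, ...) {
  cat("<trace_block>", nrow(x$values), "units x", ncol(x$values),
      "timepoints @", x$rate, "Hz;", x$modality, "/", x$kind, "\n")
  invisible(x)
}

# Bin index (1-based) containing time t, for bins [t0 + (i-1)/rate,
# t0 + i/rate).
time_to_bin <- function(t, rate, t0 = 0) {
  as.integer(floor((t - t0) * rate)) + 1L
}

# Time (bin start) of 1-based bin index i.
bin_to_time <- function(i, rate, t0 = 0) {
  t0 + (i - 1L) / rate
}

# Indices of the bins whose start times fall in [t_a, t_b), on the uniform
# grid t0 + (i-1)/rate, clamped to 1..n.  Equivalent to
# which(bt >= t_a & bt < t_b) without scanning the grid.
bin_range <- function(t_a, t_b, rate, t0, n) {
  lo <- ceiling((t_a - t0) * rate - 1e-9) + 1L
  hi <- ceiling((t_b - t0) * rate - 1e-9)
  lo <- max(1L, as.integer(lo))
  hi <- min(n, as.integer(hi))
  if (hi < lo) integer(0) else lo:hi
}

#' Collapse a cellular trace block into a bulk population signal
#'
#' Emulates a bulk photometry-like readout from single-cell recordings by
#' summing the activity of all units at every timepoint, the same way summed
#' pre-processed single-cell traces are compared with fiber-photometry
#' signals.
#'
#' @param traces a `trace_block` of cellular modality.
#' @return a single-unit `trace_block` of photometry modality, same kind.
#' @export
#' @examples
#' tb <- trace_block(matrix(1, nrow = 3, ncol = 5), rate = 20)
#' bulk_from_cells(tb)$values  # 1 x 5 matrix of 3s
bulk_from_cells <- function(traces) {
  stopifnot(inherits(traces, "trace_block"))
  if (traces$modality != "cellular") {
    stop("bulk_from_cells() expects a cellular trace_block")
  }
  if (nrow(traces$values) == 0L) stop("empty unit set")
  v <- matrix(colSums(traces$values), nrow = 1)
  trace_block(v, rate = traces$rate, t0 = traces$t0,
              modality = "photometry", kind = traces$kind)
}
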