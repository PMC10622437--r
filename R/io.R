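#' Write and read a session as plain-text files
#'
#' A session directory holds `events.csv` (one row per trial, with empty
#' cells for the events mistake trials lack), `traces.csv` and
#' `deconv.csv` (units x timepoints, one row per unit), `spikes.csv`
#' (ground-truth spike events) and `meta.json` (rate, modality, unit
#' classes and planted structure).  The same layout accepts identically
#' structured exports of real recordings, in which case the ground-truth
#' files are simply absent.
#'
#' @param session a list as returned by [simulate_session()].
#' @param dir directory to create/fill.
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a session list (without `cfg`; `truth` only if present on
#'   disk).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(session$events, file.path(dir, "events.csv"))
  data.table::fwrite(as.data.frame(session$traces$values),
                     file.path(dir, "traces.csv"), col.names = FALSE)
  data.table::fwrite(as.data.frame(session$deconv$values),
                     file.path(dir, "deconv.csv"), col.names = FALSE)
  meta <- list(rate = session$traces$rate, t0 = session$traces$t0,
               modality = session$traces$modality)
  if (!is.null(session$truth)) {
    data.table::fwrite(session$truth$spikes, file.path(dir, "spikes.csv"))
    meta$truth <- session$truth[c("unit_class", "planted_peak_phase",
                                  "planted_sequence_rank",
                                  "preferred_side")]
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$rate <- as.numeric(meta$rate)
  meta$t0 <- as.numeric(meta$t0)
  events <- as.data.frame(data.table::fread(file.path(dir, "events.csv")))
  read_mat <- function(f) {
    as.matrix(data.table::fread(file.path(dir, f), header = FALSE))
  }
  traces <- trace_block(unname(read_mat("traces.csv")), rate = meta$rate,
                        t0 = meta$t0, modality = meta$modality,
                        kind = "raw")
  deconv <- trace_block(unname(read_mat("deconv.csv")), rate = meta$rate,
                        t0 = meta$t0, modality = meta$modality,
                        kind = "deconvolved")
  out <- list(events = events, traces = traces, deconv = deconv)
  if (!is.null(meta$truth)) {
    truth <- meta$truth
    truth$spikes <- as.data.frame(
      data.table::fread(file.path(dir, "spikes.csv")))
    out$truth <- truth
  }
  out
}
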