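#' Task grammar of the delayed non-match-to-place trial
#'
#' A trial is anchored at 11 salient behavioral events (start of sample run,
#' T-junction turn, first reward, end of licking, turn towards the start box,
#' arrival at the start box, start of the choice run, T-junction turn, second
#' reward, end of licking, end of choice run).  Consecutive event pairs define
#' 10 trial phases, grouped into three task periods: encoding (E, phases
#' 1-4), maintenance (M, phases 5-6) and retrieval (R, phases 7-10).  Mistake
#' trials lack the second reward, so events 9 and 10 (and the per-phase
#' subdivision of the retrieval tail) are undefined for them.
#'
#' @return `wm_periods()` returns a named list mapping period labels
#'   (`"E"`, `"M"`, `"R"`) to the phase indices they comprise.
#' @export
#' @examples
#' wm_periods()
wm_periods <- function() {
  list(E = 1:4, M = 5:6, R = 7:10)
}

#' @rdname wm_periods
#' @return `wm_n_events()` / `wm_n_phases()` return the event and phase
#'   counts of the trial grammar (11 and 10).
#' @export
wm_n_events <- function() 11L

#' @rdname wm_periods
#' @export
wm_n_phases <- function() 10L

#' @rdname wm_periods
#' @param phase integer phase indices in 1..10.
#' @return `wm_period_of_phase()` returns the period label of each phase.
#' @export
wm_period_of_phase <- function(phase) {
  stopifnot(all(phase >= 1L), all(phase <= wm_n_phases()))
  out <- character(length(phase))
  for (p in names(wm_periods())) {
    out[phase %in% wm_periods()[[p]]] <- p
  }
  out
}

# Event-time column names used in trial event tables.
event_cols <- function() sprintf("t_event_%02d", seq_len(wm_n_events()))
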