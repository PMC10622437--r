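#' Configuration of a synthetic working-memory session
#'
#' Bundles every parameter of the synthetic-session generator.  Defaults
#' describe a typical expert miniscope session of the T-maze delayed
#' non-match-to-place task: 20 Hz acquisition, a 5-s enforced delay inside a
#' roughly 20-s trial, tens of simultaneously tracked projection neurons of
#' which about half prefer the maintenance period, and a 70-80% correct-choice
#' rate.
#'
#' @param n_trials number of trials in the session.
#' @param n_units number of recorded units (single cells).
#' @param rate acquisition rate in Hz.
#' @param median_phase_durations numeric vector of 10 median phase durations
#'   in seconds (phase k runs from event k to event k+1).
#' @param duration_jitter coefficient of variation of the multiplicative
#'   lognormal jitter applied per trial and phase (0 = fixed durations).
#' @param fractions named numeric vector with elements `E`, `M`, `R`: the
#'   proportions of units preferring each task period.  Must sum to at most
#'   1; the remainder of the population is untuned.
#' @param sequence_span seconds of the maintenance period tiled by the
#'   planted delay sequence.  Defaults to the summed median duration of the
#'   two maintenance phases.
#' @param snr amplitude-to-noise ratio of the fluorescence channel: a unit
#'   transient peak of height ~1 is corrupted by Gaussian noise with
#'   s.d. 1/snr.  Use `Inf` for noiseless traces.
#' @param p_mistake probability that a trial ends in a mistake (wrong arm).
#' @param p_left_sample probability of a leftward sample run (before the
#'   run-length cap; see [generate_events()]).
#' @param kinetics_tau exponential fluorescence decay constant in seconds
#'   (GCaMP-like kinetics).
#' @param active_rate event rate (Hz) of a tuned unit inside its preferred
#'   window.
#' @param background_rate baseline event rate (Hz) of every unit across the
#'   whole trial.
#' @param field_sd s.d. (seconds) of the temporal field of a maintenance
#'   sequence unit around its planted center.
#' @param side_modulation relative gain applied to encoding/retrieval tuned
#'   units on trials of their preferred sample side (`1 + side_modulation`
#'   on preferred-side trials, `1 - side_modulation` otherwise).
#' @param mistake_jitter s.d. of the per-spike timing jitter applied to
#'   maintenance units on mistake trials, expressed as a fraction of
#'   `sequence_span` (degrades the delay sequence).
#' @param mistake_gain multiplicative amplitude factor applied to
#'   maintenance units on mistake trials.
#' @param iti inter-trial interval in seconds.
#' @param seed integer seed; the only source of randomness of the generator.
#'
#' @return an object of class `session_config` (a validated list).
#' @seealso [simulate_session()], [generate_events()], [generate_traces()]
#' @export
#' @examples
#' cfg <- session_config(n_trials = 20, n_units = 10, seed = 1)
#' cfg$rate
session_config <- function(n_trials = 150L,
                           n_units = 60L,
                           rate = 20,
                           median_phase_durations = c(2, 1.5, 2, 1, 2, 5,
                                                      2, 1.5, 2, 1),
                           duration_jitter = 0.3,
                           fractions = c(E = 0.22, M = 0.56, R = 0.22),
                           sequence_span = sum(median_phase_durations[5:6]),
                           snr = 5,
                           p_mistake = 0.25,
                           p_left_sample = 0.5,
                           kinetics_tau = 0.6,
                           active_rate = 2,
                           background_rate = 1,
                           field_sd = 0.4,
                           side_modulation = 0.5,
                           mistake_jitter = 0.25,
                           mistake_gain = 0.6,
                           iti = 10,
                           seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), n_units = as.integer(n_units),
              rate = rate, median_phase_durations = median_phase_durations,
              duration_jitter = duration_jitter, fractions = fractions,
              sequence_span = sequence_span, snr = snr,
              p_mistake = p_mistake, p_left_sample = p_left_sample,
              kinetics_tau = kinetics_tau, active_rate = active_rate,
              background_rate = background_rate, field_sd = field_sd,
              side_modulation = side_modulation,
              mistake_jitter = mistake_jitter, mistake_gain = mistake_gain,
              iti = iti, seed = as.integer(seed))
  validate_session_config(cfg)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid session_config: ", msg,
                                 call. = FALSE)
  if (cfg$n_trials < 1L) stop_cfg("n_trials must be >= 1")
  if (cfg$n_units < 1L) stop_cfg("n_units must be >= 1")
  if (!is.finite(cfg$rate) || cfg$rate <= 0) stop_cfg("rate must be > 0")
  if (length(cfg$median_phase_durations) != wm_n_phases() ||
      any(cfg$median_phase_durations <= 0)) {
    stop_cfg("median_phase_durations must be 10 positive durations")
  }
  if (cfg$duration_jitter < 0) stop_cfg("duration_jitter must be >= 0")
  fr <- cfg$fractions
  if (!all(c("E", "M", "R") %in% names(fr)) || any(fr < 0) ||
      sum(fr[c("E", "M", "R")]) > 1 + 1e-12) {
    stop_cfg("fractions must be named E/M/R proportions summing to <= 1")
  }
  for (p in c("p_mistake", "p_left_sample")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_cfg(paste(p, "must be in [0,1]"))
  }
  if (cfg$kinetics_tau <= 0) stop_cfg("kinetics_tau must be > 0")
  if (cfg$snr <= 0) stop_cfg("snr must be > 0")
  if (cfg$sequence_span <= 0) stop_cfg("sequence_span must be > 0")
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>", x$n_trials, "trials x", x$n_units, "units @",
      x$rate, "Hz, seed", x$seed, "\n")
  cat("  fractions E/M/R:", paste(x$fractions[c("E", "M", "R")],
                                  collapse = "/"),
      " p_mistake:", x$p_mistake, " snr:", x$snr, "\n")
  invisible(x)
}

# Run a block of code under a deterministic RNG stream derived from `seed`,
# restoring the caller's RNG state afterwards.  Every stochastic operation of
# the package routes through this helper so that session seeds and
# per-operation offsets fully determine the output.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
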