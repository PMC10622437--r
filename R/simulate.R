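#' Generate the trial event table of a synthetic session
#'
#' Draws per-trial phase durations as the configured medians times a
#' multiplicative lognormal jitter (which keeps durations positive and the
#' median at its configured value), lays the trials along one session time
#' axis separated by the inter-trial interval, pseudo-randomizes the sample
#' side with no more than three consecutive runs to the same arm, and marks
#' mistake trials, whose second-reward events (9 and 10) are absent.
#'
#' @param cfg a [session_config()].
#' @param seed integer seed for this operation; defaults to the session seed.
#' @return a `data.frame` with one row per trial and columns `trial_id`,
#'   `session_id`, `side` (`"left"`/`"right"` sample run), `outcome`
#'   (`"correct"`/`"mistake"`) and `t_event_01` .. `t_event_11` (seconds;
#'   `NA` for events 9-10 of mistake trials).
#' @export
#' @examples
#' ev <- generate_events(session_config(n_trials = 5, seed = 1))
#' ev[, c("side", "outcome", "t_event_01", "t_event_11")]
generate_events <- function(cfg, seed = cfg$seed) {
  validate_session_config(cfg)
  with_rng(seed, {
    n <- cfg$n_trials
    med <- cfg$median_phase_durations
    cv <- cfg$duration_jitter
    sdlog <- sqrt(log1p(cv^2))
    # durations[k, phase]: median x lognormal jitter (median preserved)
    durations <- matrix(rep(med, each = n) *
                          exp(stats::rnorm(n * wm_n_phases(), 0, sdlog)),
                        nrow = n)
    side <- character(n)
    for (k in seq_len(n)) {
      s <- if (stats::runif(1) < cfg$p_left_sample) "left" else "right"
      if (k > 3L && all(side[(k - 3L):(k - 1L)] == s)) {
        s <- if (s == "left") "right" else "left"
      }
      side[k] <- s
    }
    outcome <- ifelse(stats::runif(n) < cfg$p_mistake, "mistake", "correct")

    events <- matrix(NA_real_, nrow = n, ncol = wm_n_events())
    t_next <- 2  # short lead-in before the first trial
    for (k in seq_len(n)) {
      events[k, ] <- t_next + c(0, cumsum(durations[k, ]))
      t_next <- events[k, wm_n_events()] + cfg$iti
    }
    out <- data.frame(trial_id = seq_len(n),
                      session_id = sprintf("sim-%d", cfg$seed),
                      side = side, outcome = outcome,
                      stringsAsFactors = FALSE)
    out[event_cols()] <- as.data.frame(events)
    out[out$outcome == "mistake", c("t_event_09", "t_event_10")] <- NA_real_
    out
  })
}

# Period-preferring class of each unit: nE/nM/nR tuned units (rounded from
# the configured fractions, capped at n_units), remainder untuned.
assign_unit_classes <- function(cfg) {
  fr <- cfg$fractions[c("E", "M", "R")]
  counts <- round(fr * cfg$n_units)
  while (sum(counts) > cfg$n_units) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  rep(c("E", "M", "R", "untuned"),
      times = c(counts, cfg$n_units - sum(counts)))
}

#' Generate GCaMP-like traces and ground truth for a synthetic session
#'
#' Units are partitioned into encoding-, maintenance- and retrieval-
#' preferring subpopulations plus an untuned remainder.  Encoding and
#' retrieval units emit extra spikes uniformly within one planted phase of
#' their period, with a gain for their preferred sample side; maintenance
#' units form a delay sequence whose per-trial activity centers tile the
#' first `sequence_span` seconds of the maintenance period in the order of
#' their planted sequence rank.  On mistake trials the maintenance sequence
#' is degraded: per-spike timing jitter proportional to the sequence span
#' and reduced amplitude.  Spikes carry gamma-distributed amplitudes (as
#' inferred spike events do), and the fluorescence channel convolves them
#' with an exponential kernel (`kinetics_tau`) on a resting baseline of 1,
#' plus Gaussian noise with s.d. `1/snr`.  The deconvolved channel is the
#' noiseless binned spike-amplitude train, a ground-truth stand-in for
#' spike inference.
#'
#' @param events trial event table from [generate_events()].
#' @param cfg the [session_config()] used to generate `events`.
#' @param seed integer seed for this operation; defaults to session seed + 1.
#' @return a list with elements `traces` (raw-fluorescence `trace_block`),
#'   `deconv` (deconvolved `trace_block`) and `truth`, a list holding
#'   `unit_class`, `planted_peak_phase`, `planted_sequence_rank` (a
#'   permutation over maintenance units, `NA` elsewhere), `preferred_side`
#'   and the `spikes` table (`unit`, `trial`, `t`, `amplitude`).
#' @export
generate_traces <- function(events, cfg, seed = cfg$seed + 1L) {
  validate_session_config(cfg)
  with_rng(seed, {
    n_units <- cfg$n_units
    rate <- cfg$rate
    unit_class <- assign_unit_classes(cfg)
    m_units <- which(unit_class == "M")
    n_m <- length(m_units)

    planted_peak_phase <- rep(NA_integer_, n_units)
    planted_peak_phase[unit_class == "E"] <-
      sample(wm_periods()$E, sum(unit_class == "E"), replace = TRUE)
    planted_peak_phase[unit_class == "R"] <-
      sample(wm_periods()$R, sum(unit_class == "R"), replace = TRUE)

    planted_sequence_rank <- rep(NA_integer_, n_units)
    if (n_m > 0L) planted_sequence_rank[m_units] <- sample.int(n_m)
    # center of a maintenance unit as a fraction of the tiled span
    center_frac <- (planted_sequence_rank - 0.5) / max(n_m, 1L)
    med_maint <- sum(cfg$median_phase_durations[wm_periods()$M])
    coverage <- min(1, cfg$sequence_span / med_maint)
    if (n_m > 0L) {
      center_s <- center_frac[m_units] * coverage * med_maint
      planted_peak_phase[m_units] <-
        ifelse(center_s < cfg$median_phase_durations[5L], 5L, 6L)
    }
    preferred_side <- rep(NA_character_, n_units)
    er <- unit_class %in% c("E", "R")
    preferred_side[er] <- sample(c("left", "right"), sum(er), replace = TRUE)

    ev <- as.matrix(events[event_cols()])
    n_trials <- cfg$n_trials
    t1 <- ev[, 1L]; t11 <- ev[, wm_n_events()]
    mistake <- events$outcome == "mistake"

    # expand Poisson counts per (unit, trial) cell into flat spike vectors
    expand <- function(counts, unit, trial) {
      list(unit = rep(unit, counts), trial = rep(trial, counts))
    }
    # background: homogeneous over the whole trial, every unit
    grid_u <- rep(seq_len(n_units), times = n_trials)
    grid_k <- rep(seq_len(n_trials), each = n_units)
    n_bg <- stats::rpois(n_units * n_trials,
                         cfg$background_rate * (t11 - t1)[grid_k])
    bg <- expand(n_bg, grid_u, grid_k)
    bg_t <- stats::runif(length(bg$unit), t1[bg$trial], t11[bg$trial])
    bg_a <- stats::rgamma(length(bg$unit), shape = 3, rate = 3)

    # encoding / retrieval tuned units: uniform within the planted phase,
    # gain for the preferred sample side
    er_units <- which(unit_class %in% c("E", "R"))
    er_t <- er_a <- numeric(0); er_id <- list(unit = integer(0),
                                              trial = integer(0))
    if (length(er_units)) {
      gu <- rep(er_units, times = n_trials)
      gk <- rep(seq_len(n_trials), each = length(er_units))
      ph <- planted_peak_phase[gu]
      a <- ev[cbind(gk, ph)]; b <- ev[cbind(gk, ph + 1L)]
      gain <- ifelse(events$side[gk] == preferred_side[gu],
                     1 + cfg$side_modulation, 1 - cfg$side_modulation)
      lambda <- cfg$active_rate * (b - a) * gain
      lambda[!is.finite(lambda)] <- 0  # planted phase absent (mistake tail)
      n_act <- stats::rpois(length(gu), lambda)
      er_id <- expand(n_act, gu, gk)
      lo <- rep(a, n_act); hi <- rep(b, n_act)
      er_t <- stats::runif(length(er_id$unit), lo, hi)
      er_a <- stats::rgamma(length(er_id$unit), shape = 3, rate = 3)
    }

    # maintenance sequence units: gaussian field around the planted center;
    # mistake trials add timing jitter and reduced amplitude
    m_t <- m_a <- numeric(0); m_id <- list(unit = integer(0),
                                           trial = integer(0))
    if (n_m > 0L) {
      gu <- rep(m_units, times = n_trials)
      gk <- rep(seq_len(n_trials), each = n_m)
      center <- ev[gk, 5L] + center_frac[gu] * coverage *
        (ev[gk, 7L] - ev[gk, 5L])
      lambda <- cfg$active_rate * cfg$field_sd * sqrt(2 * pi)
      n_act <- stats::rpois(length(gu), lambda)
      m_id <- expand(n_act, gu, gk)
      m_t <- stats::rnorm(length(m_id$unit), rep(center, n_act),
                          cfg$field_sd)
      m_a <- stats::rgamma(length(m_id$unit), shape = 3, rate = 3)
      mist_sp <- mistake[m_id$trial]
      if (any(mist_sp)) {
        m_t[mist_sp] <- m_t[mist_sp] +
          stats::rnorm(sum(mist_sp), 0,
                       cfg$mistake_jitter * cfg$sequence_span)
        m_a[mist_sp] <- m_a[mist_sp] * cfg$mistake_gain
      }
    }

    spikes_df <- data.frame(
      unit = c(bg$unit, er_id$unit, m_id$unit),
      trial = c(bg$trial, er_id$trial, m_id$trial),
      t = c(bg_t, er_t, m_t),
      amplitude = c(bg_a, er_a, m_a))
    # clamp to trial bounds
    spikes_df$t <- pmin(pmax(spikes_df$t, t1[spikes_df$trial]),
                        t11[spikes_df$trial] - 1e-6)
    spikes_df <- spikes_df[order(spikes_df$trial, spikes_df$unit), ]
    rownames(spikes_df) <- NULL

    n_bins <- time_to_bin(max(t11) + 2, rate)
    deconv <- matrix(0, nrow = n_units, ncol = n_bins)
    li <- (time_to_bin(spikes_df$t, rate) - 1L) * n_units + spikes_df$unit
    acc <- rowsum(spikes_df$amplitude, li)
    deconv[as.integer(rownames(acc))] <- acc[, 1L]
    decay <- exp(-1 / (cfg$kinetics_tau * rate))
    # stats::filter runs the recursion down each column; strip ts attributes
    fluor <- t(matrix(as.numeric(stats::filter(t(deconv), decay,
                                               method = "recursive")),
                      nrow = n_bins, ncol = n_units))
    noise_sd <- if (is.finite(cfg$snr)) 1 / cfg$snr else 0
    if (noise_sd > 0) {
      fluor <- fluor + matrix(stats::rnorm(length(fluor), 0, noise_sd),
                              nrow = n_units)
    }
    fluor <- fluor + 1  # resting fluorescence baseline

    list(traces = trace_block(fluor, rate = rate, modality = "cellular",
                              kind = "raw"),
         deconv = trace_block(deconv, rate = rate, modality = "cellular",
                              kind = "deconvolved"),
         truth = list(unit_class = unit_class,
                      planted_peak_phase = planted_peak_phase,
                      planted_sequence_rank = planted_sequence_rank,
                      preferred_side = preferred_side,
                      spikes = spikes_df))
  })
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper chaining [generate_events()] and [generate_traces()]
#' with per-operation seed streams derived from the session seed.
#'
#' @param cfg a [session_config()].
#' @return a list with elements `cfg`, `events`, `traces`, `deconv`, `truth`.
#' @export
#' @examples
#' sess <- simulate_session(session_config(n_trials = 10, n_units = 8,
#'                                         seed = 42))
#' table(sess$truth$unit_class)
simulate_session <- function(cfg) {
  events <- generate_events(cfg, seed = cfg$seed)
  tr <- generate_traces(events, cfg, seed = cfg$seed + 1L)
  list(cfg = cfg, events = events, traces = tr$traces, deconv = tr$deconv,
       truth = tr$truth)
}
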