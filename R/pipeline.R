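#' Check a trial event table against the task grammar
#'
#' Reports trials whose present event times are not strictly increasing,
#' correct trials with missing events, and mistake trials that contain the
#' second-reward events (9 or 10), which the task cannot produce.
#'
#' @param events trial event table.
#' @return a `data.frame` with columns `trial_id` and `violation`
#'   (zero rows for a clean table).
#' @export
validate_events <- function(events) {
  ev <- as.matrix(events[event_cols()])
  out <- list()
  flag <- function(k, msg) {
    out[[length(out) + 1L]] <<- data.frame(trial_id = events$trial_id[k],
                                           violation = msg)
  }
  for (k in seq_len(nrow(events))) {
    times <- ev[k, ]
    present <- which(is.finite(times))
    if (any(diff(times[present]) <= 0)) {
      flag(k, "event times not strictly increasing")
    }
    if (events$outcome[k] == "correct") {
      if (length(present) < wm_n_events()) flag(k, "missing mandatory event")
    } else {
      if (any(is.finite(times[c(9L, 10L)]))) {
        flag(k, "mistake trial contains reward events 9/10")
      }
      if (any(!is.finite(times[-c(9L, 10L)]))) {
        flag(k, "missing mandatory event")
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(trial_id = integer(), violation = character()))
  }
  do.call(rbind, out)
}

#' Default pipeline configuration
#'
#' All stage parameters of a full synthetic-session run, with the
#' analysis defaults used throughout the package: 1-s baseline window,
#' alpha 0.01, 100 draws x 20 repetitions and a 3-bin moving window for
#' the ROC stage, and 1000 permutations for the orderability and decoding
#' nulls.
#'
#' @param seed integer master seed; per-stage streams are derived from it.
#' @param out_dir output directory for stage tables and the summary.
#' @return a nested configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "wmtrace-run") {
  list(seed = as.integer(seed),
       out_dir = out_dir,
       stages = c("simulate", "align", "phasepref", "roc", "bdo",
                  "sequence", "decode"),
       session = list(),
       alpha = 0.01,
       baseline_window = 1,
       roc = list(n_draw = 100L, n_rep = 20L, window = 3L,
                  contrast = "outcome", stratify_side = "left",
                  period = "M"),
       bdo = list(n_perm = 1000L, span = "M"),
       sequence = list(span = "M"),
       decode = list(n_perm = 1000L, contrast = "side"))
}

# Strict-schema merge of a user config into the defaults.
merge_run_config <- function(config) {
  base <- default_run_config()
  check <- function(user, ref, path = "") {
    bad <- setdiff(names(user), names(ref))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "), call. = FALSE)
    }
  }
  check(config, base)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) && nm != "session") {
      check(config[[nm]], base[[nm]], paste0(nm, "$"))
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   keys; unknown keys are rejected.
#' @return the merged configuration list.
#' @export
read_run_config <- function(path) {
  merge_run_config(yaml::read_yaml(path))
}

# Small stable FNV-1a style hash of the configuration for provenance.
# The output location does not affect the analysis, so it is excluded.
config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full synthetic-session analysis pipeline
#'
#' Executes the enabled stages — simulate, align, phase preference,
#' time-resolved ROC, orderability, sequence train/test and transient
#' decoding — on one seeded synthetic session, writes each stage's tables
#' as CSV plus a machine-readable `summary.json` (with a provenance
#' block), and returns the summary invisibly.
#'
#' @param config a configuration list (see [default_run_config()]), or a
#'   path to a YAML file.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  log_stage <- function(name, t0) {
    message(sprintf("[wmtrace] %-9s %6.2f s", name,
                    as.numeric(Sys.time()) - t0))
  }
  summary <- list()
  out <- function(...) file.path(config$out_dir, ...)

  if (!"simulate" %in% stages) stop("pipeline requires the simulate stage")
  t0 <- as.numeric(Sys.time())
  cfg <- do.call(session_config,
                 c(config$session,
                   if (is.null(config$session$seed)) list(seed = config$seed)))
  sess <- simulate_session(cfg)
  data.table::fwrite(sess$events, out("events.csv"))
  viol <- validate_events(sess$events)
  if (nrow(viol) > 0L) stop("generated events violate the task grammar")
  log_stage("simulate", t0)

  aligned_z <- NULL; aligned_d <- NULL
  if ("align" %in% stages) {
    t0 <- as.numeric(Sys.time())
    aligned_z <- build_aligned_tensor(sess$events, sess$traces,
                                      signal = "zscore",
                                      baseline_window = config$baseline_window)
    aligned_d <- build_aligned_tensor(sess$events, sess$deconv,
                                      signal = "deconvolved")
    log_stage("align", t0)
  }
  need_aligned <- function(stage) {
    if (is.null(aligned_z)) {
      stop("stage '", stage, "' needs the align stage outputs; ",
           "enable 'align' in config$stages")
    }
  }

  if ("phasepref" %in% stages) {
    t0 <- as.numeric(Sys.time())
    means <- window_mean_activity(sess$events, sess$deconv,
                                  windows = "periods")
    st <- phase_significance(means)
    frac <- preference_fractions(st)
    act <- preferred_window_activity(means, st)
    counts <- round(frac * nrow(st$p))
    utils::write.csv(data.frame(unit = seq_len(nrow(st$p)), st$p),
                     out("period_significance.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(coactivity_matrix(
      binarize(st, config$alpha))), out("coactivity_periods.csv"))
    summary$preferred_fractions <- as.list(frac)
    summary$preferred_activity <- as.list(act)
    summary$period_enrichment_p <-
      as.list(period_preference_test(counts, nrow(st$p)))
    log_stage("phasepref", t0)
  }

  if ("roc" %in% stages) {
    need_aligned("roc")
    t0 <- as.numeric(Sys.time())
    sel <- sess$events$side == config$roc$stratify_side
    tens <- aligned_z
    tens$values <- tens$values[sel, , , drop = FALSE]
    tens$labels <- tens$labels[sel, , drop = FALSE]
    lab <- tens$labels$outcome
    span <- tensor_span(tens, config$roc$period)
    auc <- time_resolved_auc(tens, lab, span = span,
                             n_draw = config$roc$n_draw,
                             n_rep = config$roc$n_rep,
                             window = config$roc$window,
                             alpha = config$alpha,
                             seed = config$seed + 101L)
    utils::write.csv(data.frame(bin = auc$t, auc_mean = auc$auc_mean,
                                auc_sem = auc$auc_sem,
                                shuffle_mean = auc$shuffle_mean,
                                shuffle_sem = auc$shuffle_sem,
                                p_raw = auc$p_raw, p_adj = auc$p_adj,
                                sig = auc$sig_mask),
                     out("roc.csv"), row.names = FALSE)
    summary$roc_significant_bins <- sum(auc$sig_mask)
    summary$roc_bins <- length(auc$t)
    log_stage("roc", t0)
  }

  if ("bdo" %in% stages) {
    need_aligned("bdo")
    t0 <- as.numeric(Sys.time())
    centers <- trial_center_matrix(aligned_d, span = config$bdo$span)
    bm <- bdo_matrix(centers)
    pt <- abdo_permutation_test(centers, n_perm = config$bdo$n_perm,
                                seed = config$seed + 202L)
    utils::write.csv(bm$bdo, out("bdo_matrix.csv"))
    summary$abdo <- bm$abdo
    summary$abdo_perm_p <- pt$perm_p
    log_stage("bdo", t0)
  }

  if ("sequence" %in% stages) {
    need_aligned("sequence")
    t0 <- as.numeric(Sys.time())
    sq <- sequence_analysis(aligned_d, span = config$sequence$span,
                            seed = config$seed + 303L)
    summary$sequence <- list(
      median_shift_test = sq$shift_test$median,
      p75_shift_test = sq$shift_test$p75,
      median_shift_mistake =
        if (is.null(sq$shift_mistake)) NA else sq$shift_mistake$median,
      p_compare = sq$p_compare)
    log_stage("sequence", t0)
  }

  if ("decode" %in% stages) {
    need_aligned("decode")
    t0 <- as.numeric(Sys.time())
    dec <- l2_permutation_test(aligned_d,
                               sess$events[[config$decode$contrast]],
                               n_perm = config$decode$n_perm,
                               seed = config$seed + 404L)
    utils::write.csv(data.frame(bin = dec$t, l2 = dec$l2, p = dec$p,
                                neg_log10_p = dec$neg_log10_p),
                     out("decode.csv"), row.names = FALSE)
    summary$decode_bins_p01 <- sum(dec$p <= config$alpha)
    log_stage("decode", t0)
  }

  summary$provenance <- list(
    package = "wmtrace",
    version = as.character(utils::packageVersion("wmtrace")),
    seed = config$seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
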