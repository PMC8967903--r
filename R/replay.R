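# End-to-end "replay" pipeline on synthetic data: generation -> preprocessing
# -> tuning -> state-conditioned decoding under the control conditions ->
# reliability -> LIF simulation, with a machine-readable, fully deterministic
# report.

#' Configuration for an end-to-end replay
#'
#' @param seed global seed; fanned out deterministically to every stage with
#'   [child_seed()].
#' @param scenario synthetic scenario name (see [synth_config()]).
#' @param n_sessions number of synthetic sessions.
#' @param n_neurons,n_reps session size (25 repetitions per direction by
#'   default so that balanced cells comfortably clear the eligibility rule).
#' @param conditions decoding conditions to run; subset of `"baseline"`,
#'   `"shuffled"`, `"exclude_running_positive"`, `"shuffled_exclude"`,
#'   `"rel25"`, `"rel50"`.
#' @param n_splits decoding train/test splits.
#' @param n_perm tuning-test permutations.
#' @param min_cell_trials eligibility: minimum balanced trials per
#'   (direction, state) cell.
#' @param min_neurons eligibility: minimum neurons per session.
#' @param run_lif include the LIF stage?
#' @param lif_peaks,lif_noise_vars,lif_runs LIF grid settings.
#' @param outdir optional directory; when set, the report is written to
#'   `replay_report.json` there.
#' @return a list of class `replay_config`.
#' @export
replay_config <- function(seed = 1, scenario = "reliability_gap", n_sessions = 8,
                          n_neurons = 100, n_reps = 25,
                          conditions = c("baseline", "shuffled",
                                         "exclude_running_positive",
                                         "shuffled_exclude", "rel25", "rel50"),
                          n_splits = 10, n_perm = 100,
                          min_cell_trials = 5, min_neurons = 10,
                          run_lif = TRUE,
                          lif_peaks = c(0.1, 0.2, 0.4, 0.6, 0.8),
                          lif_noise_vars = c(19, 36), lif_runs = 5,
                          outdir = NULL) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  structure(as.list(environment()), class = "replay_config")
}

# Decoding for one named condition on one session.
decode_condition <- function(cond, tm_bal, tuning, relrec, n_splits, seed) {
  tm <- tm_bal
  flags <- list(shuffled = FALSE, exclusion = "none", k_percent = NULL)
  if (cond %in% c("exclude_running_positive", "shuffled_exclude")) {
    tm <- exclude_neurons(tm, "running_positive", tuning)
    flags$exclusion <- "running_positive"
  }
  if (cond %in% c("rel25", "rel50")) {
    k <- if (cond == "rel25") 25 else 50
    tm <- exclude_neurons(tm, "reliability_top_k", relrec, k_percent = k)
    flags$exclusion <- "reliability_top_k"
    flags$k_percent <- k
  }
  if (cond %in% c("shuffled", "shuffled_exclude")) {
    tm <- shuffle_within_class(tm, seed = child_seed(seed, paste0("shuf-", cond)))
    flags$shuffled <- TRUE
  }
  fit_eval_mlr(tm, n_splits = n_splits, seed = child_seed(seed, paste0("mlr-", cond)),
               condition = flags)
}

#' Run the full synthetic replay pipeline
#'
#' Generates `n_sessions` synthetic sessions under the configured scenario,
#' extracts and balances trials, classifies running-speed tuning, decodes
#' grating direction separately for running and stationary trials under each
#' configured control condition, computes per-neuron reliability records, the
#' paired signed-rank comparison of states per condition, and the regression
#' of the decoding gap on the session-mean reliability change, and (optionally)
#' runs the LIF noise grid. The report is fully deterministic given the seed.
#'
#' @param config a [replay_config()].
#' @return a list of class `replay_report` (also written as JSON when
#'   `config$outdir` is set).
#' @export
replay <- function(config = replay_config()) {
  stopifnot(inherits(config, "replay_config"))
  seed <- config$seed
  scfg <- synth_config(scenario = config$scenario, n_neurons = config$n_neurons,
                       n_reps = config$n_reps)
  sessions <- list()
  for (i in seq_len(config$n_sessions)) {
    b <- generate_session(scfg, seed = child_seed(seed, paste0("session", i)))
    b$session_id <- sprintf("%s-%02d", b$session_id, i)
    sessions[[i]] <- b
  }

  per_session <- list()
  decoded <- list()
  for (i in seq_along(sessions)) {
    b <- sessions[[i]]
    sseed <- child_seed(seed, paste0("stage-", i))
    tm <- suppressMessages(extract_trial_responses(b))
    tm_bal <- suppressMessages(balance_trials(tm, seed = child_seed(sseed, "balance")))
    n_cell <- cell_counts(tm_bal)[1, 1]
    eligible <- ncol(tm_bal$responses) >= config$min_neurons &&
      n_cell >= config$min_cell_trials
    qc <- session_qc(b)
    row <- list(session_id = b$session_id, qc_speed_tuning = as.logical(qc),
                run_frac = attr(qc, "run_frac"), max_speed = attr(qc, "max_speed"),
                trials_per_cell = as.integer(n_cell), eligible_decoding = eligible)
    if (!eligible) {
      row$excluded_reason <- "insufficient balanced trials or neurons"
      per_session[[i]] <- row
      next
    }
    tuning <- tune_session(b, "speed", "stimulus", n_perm = config$n_perm,
                           seed = child_seed(sseed, "tuning"))
    relrec <- reliability_by_state(tm_bal)
    res_cond <- lapply(config$conditions, decode_condition, tm_bal = tm_bal,
                       tuning = tuning, relrec = relrec,
                       n_splits = config$n_splits, seed = sseed)
    names(res_cond) <- config$conditions
    decoded[[b$session_id]] <- res_cond
    rel_ok <- relrec[is.finite(relrec$rel_stationary) & relrec$rel_stationary > 0, ]
    row$tuned_fraction <- mean(tuning$levene_p < 0.05)
    row$tclass_counts <- as.list(table(tuning$tclass))
    row$mean_delta_rel <- mean(relrec$delta_rel, na.rm = TRUE)
    row$mean_pct_change_rel <- mean(100 * rel_ok$delta_rel / rel_ok$rel_stationary)
    row$accuracy <- lapply(res_cond, function(r)
      list(running = r$accuracy_running, stationary = r$accuracy_stationary))
    per_session[[i]] <- row
  }

  used <- names(decoded)
  comparisons <- list()
  if (length(used) >= 6) {
    for (cond in config$conditions) {
      cs <- compare_states(lapply(decoded, `[[`, cond))
      comparisons[[cond]] <- list(statistic = cs$statistic, p = cs$p, n = cs$n,
                                  mean_gap = cs$mean_diff,
                                  gap_positive = cs$mean_diff > 0)
    }
  }

  regression <- NULL
  if (length(used) >= 6 && "baseline" %in% config$conditions) {
    gaps <- vapply(decoded, function(r)
      r$baseline$accuracy_running - r$baseline$accuracy_stationary, numeric(1))
    elig <- vapply(per_session, function(r) isTRUE(r$eligible_decoding), logical(1))
    drel <- vapply(per_session[elig], function(r) r$mean_pct_change_rel, numeric(1))
    if (var(drel) > 0) {
      ow <- ols_wald(drel, gaps, n_boot = 1000, seed = child_seed(seed, "olswald"))
      regression <- list(slope = ow$slope, p = ow$p, n = ow$n)
    }
  }

  lif <- NULL
  if (config$run_lif) {
    gr <- run_lif_experiment(lif_config(), peak_currents = config$lif_peaks,
                             noise_vars = config$lif_noise_vars,
                             n_runs = config$lif_runs,
                             seed = child_seed(seed, "lif"))
    lif <- gr$summary
  }

  report <- list(
    config = list(seed = seed, scenario = config$scenario,
                  n_sessions = config$n_sessions, n_neurons = config$n_neurons,
                  n_reps = config$n_reps, conditions = config$conditions,
                  n_splits = config$n_splits, n_perm = config$n_perm),
    provenance = replay_provenance(),
    sessions = per_session,
    state_comparisons = comparisons,
    gap_vs_reliability_regression = regression,
    lif_grid = lif
  )
  class(report) <- "replay_report"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_json(report), file.path(config$outdir, "replay_report.json"))
  }
  report
}

# Serialise a replay report deterministically.
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(15),
                                dataframe = "columns", null = "null", pretty = TRUE))
}

# Defaults of record with their meaning, emitted with every report.
replay_provenance <- function() {
  list(
    dff_mode_kernel_frames = list(value = 5400, meaning = "rolling-mode baseline window (3 min at 30 Hz)"),
    dff_mean_kernel_frames = list(value = 3000, meaning = "rolling-mean smoothing of the mode baseline"),
    response_window_s = list(value = 2, meaning = "trial response window (s)"),
    response_offset_frames = list(value = 10, meaning = "window offset from stimulus onset (330 ms at 30 Hz)"),
    running_mean_speed_cm_s = list(value = 3, meaning = "trial running iff mean speed above this and min >= 0.5"),
    stationary_mean_speed_cm_s = list(value = 0.5, meaning = "trial stationary iff mean speed below this and max <= 3"),
    tuning_bins = list(value = 20, meaning = "quantile bins of the covariate for tuning curves"),
    tuning_alpha = list(value = 0.05, meaning = "per-neuron significance level, uncorrected"),
    decoder = list(value = "multinomial logistic regression, unpenalized",
                   meaning = "8-way direction decoder, 10 x 50:50 stratified splits"),
    lif_parameters = list(value = "C_m 490 pF, g_l 16 nS, E_l -65 mV, V_thresh -49 mV, V_init -70 mV, dt 0.05 ms",
                          meaning = "membrane constants of the LIF simulation"),
    lif_noise_pair_mV2 = list(value = c(19, 36), meaning = "membrane-noise variances emulating running/stationary states")
  )
}

#' @export
print.replay_report <- function(x, ...) {
  cat(sprintf("<replay_report: scenario %s, seed %s, %d sessions>\n",
              x$config$scenario, x$config$seed, x$config$n_sessions))
  for (cond in names(x$state_comparisons)) {
    cmp <- x$state_comparisons[[cond]]
    cat(sprintf("  %-26s gap %+0.3f  (signed-rank p = %.4g, n = %d)\n",
                cond, cmp$mean_gap, cmp$p, cmp$n))
  }
  if (!is.null(x$gap_vs_reliability_regression))
    cat(sprintf("  gap ~ reliability change: slope %.4g, p = %.3g\n",
                x$gap_vs_reliability_regression$slope, x$gap_vs_reliability_regression$p))
  invisible(x)
}
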