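# Preprocessing: rolling-baseline dF/F, locomotor-state labelling of trial
# windows, trial-response extraction, and class-balanced subsampling.

#' Compute dF/F with a rolling mean-of-mode baseline
#'
#' The baseline is a centered rolling mean (width `mean_kernel_frames`) of a
#' centered rolling mode (width `mode_kernel_frames`) of the raw trace; the
#' returned trace is `(raw - baseline) / baseline`. Both windows are truncated
#' at the trace edges. The mode of a real-valued trace is taken over values
#' binned at a fixed resolution relative to the trace median
#' (`bin_resolution * median(raw)`), which makes the result exactly invariant
#' to multiplicative rescaling of the raw fluorescence.
#'
#' @param raw raw (neuropil-corrected) fluorescence vector.
#' @param mode_kernel_frames rolling-mode window width (default 5400 frames,
#'   3 min at 30 Hz).
#' @param mean_kernel_frames rolling-mean window width (default 3000 frames).
#' @param bin_resolution bin width for the mode, as a fraction of the median.
#' @return dF/F vector with the baseline attached as attribute `"baseline"`.
#' @export
compute_dff <- function(raw, mode_kernel_frames = 5400, mean_kernel_frames = 3000,
                        bin_resolution = 1e-3) {
  stopifnot(is.numeric(raw), mode_kernel_frames >= 1, mean_kernel_frames >= 1)
  n <- length(raw)
  if (n <= mode_kernel_frames)
    stop("trace must be longer than the mode kernel")
  if (diff(range(raw)) == 0) {
    baseline <- raw
  } else {
    w <- bin_resolution * median(raw)
    if (!is.finite(w) || w <= 0)
      stop("degenerate fluorescence: non-positive median, cannot form baseline bins")
    lo <- min(raw)
    ids <- pmin(floor((raw - lo) / w), floor((max(raw) - lo) / w))
    n_bins <- as.integer(max(ids) + 1)
    mode_ids <- roll_mode_cpp(as.integer(ids), floor(mode_kernel_frames / 2), n_bins)
    mode_val <- lo + (mode_ids + 0.5) * w
    baseline <- roll_mean_trunc(mode_val, mean_kernel_frames)
  }
  if (any(baseline <= 0))
    stop("degenerate fluorescence: baseline <= 0")
  structure((raw - baseline) / baseline, baseline = baseline)
}

#' Classify the locomotor state of a trial window
#'
#' Running: mean speed > 3 cm/s and minimum speed >= 0.5 cm/s. Stationary:
#' mean speed < 0.5 cm/s and maximum speed <= 3 cm/s. Anything else is
#' `"ambiguous"` and is excluded from state-conditioned analyses.
#'
#' @param speed_window speeds (cm/s) over the trial's response window.
#' @return `"running"`, `"stationary"`, or `"ambiguous"`.
#' @export
classify_trial_state <- function(speed_window) {
  if (length(speed_window) == 0) stop("empty speed window")
  if (any(speed_window < 0)) stop("negative speeds are invalid")
  m <- mean(speed_window)
  if (m > 3 && min(speed_window) >= 0.5) return("running")
  if (m < 0.5 && max(speed_window) <= 3) return("stationary")
  "ambiguous"
}

#' Construct a trial matrix
#'
#' @param responses trials x neurons numeric matrix (column names = neuron ids).
#' @param class_label per-trial stimulus class (grating direction, degrees).
#' @param state per-trial locomotor state.
#' @param tf optional per-trial temporal-frequency label.
#' @param window_s,offset_frames,source_session provenance fields.
#' @return a list of class `trial_matrix`.
#' @export
trial_matrix <- function(responses, class_label, state, tf = NULL,
                         window_s = NA_real_, offset_frames = NA_integer_,
                         source_session = NA_character_) {
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == length(class_label), length(state) == length(class_label))
  if (anyNA(responses)) stop("trial responses must not contain missing values")
  structure(list(responses = responses,
                 class_label = as.character(class_label),
                 state = as.character(state),
                 tf = if (is.null(tf)) rep(NA_real_, length(class_label)) else tf,
                 window_s = window_s, offset_frames = offset_frames,
                 source_session = source_session),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix %s: %d trials x %d neurons>\n",
              x$source_session, nrow(x$responses), ncol(x$responses)))
  print(table(class = x$class_label, state = x$state))
  invisible(x)
}

#' Extract per-trial population responses from a session bundle
#'
#' One row per drifting-grating epoch: the per-neuron mean dF/F over a window
#' of `window_s` seconds starting `offset_frames` frames after stimulus onset
#' (the window may extend past the grating into the following blank, as in the
#' 330 ms-offset design). The locomotor state is classified from the speed
#' trace over the same frames. Trials whose window overruns the recording are
#' dropped with a warning.
#'
#' @param bundle a `session_bundle`.
#' @param window_s response-window length in seconds.
#' @param offset_frames onset offset in frames.
#' @return a `trial_matrix`.
#' @export
extract_trial_responses <- function(bundle, window_s = 2.0, offset_frames = 10L) {
  stopifnot(inherits(bundle, "session_bundle"))
  wf <- round(window_s * bundle$frame_rate)
  grat <- bundle$stim_table[bundle$stim_table$epoch_type == "drifting_grating", ]
  if (nrow(grat) == 0) stop("no drifting-grating epochs in stimulus table")
  n_frames <- ncol(bundle$dff)
  keep <- grat$start_frame + offset_frames + wf <= n_frames
  if (any(!keep))
    warning(sprintf("dropped %d trial(s) whose response window overruns the recording",
                    sum(!keep)))
  grat <- grat[keep, , drop = FALSE]
  resp <- matrix(NA_real_, nrow(grat), nrow(bundle$dff),
                 dimnames = list(NULL, rownames(bundle$dff)))
  st <- character(nrow(grat))
  for (t in seq_len(nrow(grat))) {
    idx <- (grat$start_frame[t] + offset_frames + 1L):(grat$start_frame[t] + offset_frames + wf)
    resp[t, ] <- rowMeans(bundle$dff[, idx, drop = FALSE])
    st[t] <- classify_trial_state(bundle$speed[idx])
  }
  trial_matrix(resp, grat$direction, st, tf = grat$temporal_frequency,
               window_s = window_s, offset_frames = as.integer(offset_frames),
               source_session = bundle$session_id)
}

# (class, state) cell counts of a trial matrix, states restricted to
# running/stationary.
cell_counts <- function(tm) {
  keep <- tm$state %in% c("running", "stationary")
  table(class = tm$class_label[keep], state = tm$state[keep])
}

# Row-subset a trial matrix.
tm_subset <- function(tm, rows) {
  trial_matrix(tm$responses[rows, , drop = FALSE], tm$class_label[rows],
               tm$state[rows], tm$tf[rows], tm$window_s, tm$offset_frames,
               tm$source_session)
}

#' Balance trial counts across (class, state) cells
#'
#' Ambiguous-state trials are removed, then every (direction, state) cell is
#' subsampled without replacement to the size of the smallest cell, so both
#' locomotor states contribute identical class-conditional trial counts.
#'
#' @param tm a `trial_matrix`.
#' @param seed integer seed or `NULL`.
#' @return a balanced `trial_matrix`.
#' @export
balance_trials <- function(tm, seed = NULL) {
  stopifnot(inherits(tm, "trial_matrix"))
  amb <- tm$state == "ambiguous"
  if (any(amb)) {
    message(sprintf("balance_trials: removing %d ambiguous-state trial(s)", sum(amb)))
    tm <- tm_subset(tm, !amb)
  }
  classes <- sort(unique(tm$class_label))
  states <- c("running", "stationary")
  counts <- sapply(states, function(s) sapply(classes, function(cl)
    sum(tm$class_label == cl & tm$state == s)))
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty (class, state) cell: direction %s during %s",
                 classes[bad[1]], states[bad[2]]))
  }
  n_star <- min(counts)
  with_seed(seed, {
    keep <- integer(0)
    for (cl in classes) for (s in states) {
      rows <- which(tm$class_label == cl & tm$state == s)
      keep <- c(keep, rows[sample.int(length(rows), n_star)])
    }
    tm_subset(tm, sort(keep))
  })
}
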