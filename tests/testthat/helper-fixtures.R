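# Shared fixtures and independent oracles, built in code at test time.

# Minimal hand-crafted session bundle (bypasses the generator) for tests that
# need full control over traces and epochs.
make_bundle <- function(dff, speed, stim_table, pupil = NULL, frame_rate = 30,
                        region = "VISp", layer = "L2/3", id = "crafted") {
  structure(list(dff = dff, speed = speed,
                 pupil = if (is.null(pupil)) rep(1, length(speed)) else pupil,
                 stim_table = stim_table, frame_rate = frame_rate,
                 region = region, layer = layer, session_id = id,
                 truth = NULL, config = NULL),
            class = "session_bundle")
}

# Stimulus table of n_trials gratings (stim_f frames) separated by blanks,
# starting at frame `lead` (0-based, inclusive-exclusive convention).
make_stim_table <- function(directions, stim_f = 60, blank_f = 30, lead = 0,
                            tf = NULL) {
  n <- length(directions)
  rows <- list()
  cursor <- lead
  for (t in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      epoch_type = "drifting_grating", start_frame = cursor,
      end_frame = cursor + stim_f, direction = directions[t],
      temporal_frequency = if (is.null(tf)) NA_real_ else tf[t])
    cursor <- cursor + stim_f
    rows[[length(rows) + 1]] <- data.frame(
      epoch_type = "blank", start_frame = cursor, end_frame = cursor + blank_f,
      direction = NA_real_, temporal_frequency = NA_real_)
    cursor <- cursor + blank_f
  }
  do.call(rbind, rows)
}

# Trial matrix with planted class means: responses = mean[class, neuron]
# (+ iid noise), equal trials per (class, state) cell.
make_planted_tm <- function(class_means, n_per_cell = 6, noise_sd = 0,
                            states = c("running", "stationary"), seed = 1) {
  classes <- rownames(class_means)
  rows <- expand.grid(rep = seq_len(n_per_cell), class = classes, state = states,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  resp <- class_means[rows$class, , drop = FALSE] +
    matrix(rnorm(nrow(rows) * ncol(class_means), 0, noise_sd),
           nrow(rows), ncol(class_means))
  rownames(resp) <- NULL
  colnames(resp) <- colnames(class_means)
  trial_matrix(resp, rows$class, rows$state, source_session = "planted")
}

# Independent brute-force oracle for the dF/F baseline: binned rolling mode
# (lowest-bin tie break) followed by a truncated centered rolling mean,
# computed with plain loops.
brute_baseline <- function(raw, mode_k, mean_k, bin_resolution = 1e-3) {
  n <- length(raw)
  w <- bin_resolution * median(raw)
  lo <- min(raw)
  ids <- pmin(floor((raw - lo) / w), floor((max(raw) - lo) / w))
  hm <- floor(mode_k / 2)
  mode_val <- numeric(n)
  for (i in seq_len(n)) {
    win <- ids[max(1, i - hm):min(n, i + hm)]
    tab <- table(win)
    best <- min(as.integer(names(tab)[tab == max(tab)]))
    mode_val[i] <- lo + (best + 0.5) * w
  }
  hm2 <- floor(mean_k / 2)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(mode_val[max(1, i - hm2):min(n, i + hm2)])
  out
}

# Mean pairwise correlation between neurons across trials, within
# (class, state) cells, averaged over cells (noise-correlation oracle).
mean_within_cell_corr <- function(tm, max_neurons = 30) {
  jj <- seq_len(min(ncol(tm$responses), max_neurons))
  cells <- split(seq_along(tm$class_label),
                 list(tm$class_label, tm$state), drop = TRUE)
  vals <- c()
  for (rows in cells) {
    if (length(rows) < 3) next
    cm <- suppressWarnings(cor(tm$responses[rows, jj]))
    vals <- c(vals, cm[upper.tri(cm)])
  }
  mean(vals, na.rm = TRUE)
}

# Run the standard scenario pipeline on one generated session; returns NULL
# when the balanced cells are too small for decoding.
scenario_session <- function(seed, scenario = "reliability_gap", n_reps = 25,
                             n_neurons = 100, min_cell = 5, with_tuning = TRUE) {
  cfg <- synth_config(scenario = scenario, n_neurons = n_neurons, n_reps = n_reps)
  b <- generate_session(cfg, seed = seed)
  tm <- suppressWarnings(suppressMessages(extract_trial_responses(b)))
  tmb <- suppressMessages(balance_trials(tm, seed = child_seed(seed, "bal")))
  if (min(table(tmb$class_label, tmb$state)) < min_cell) return(NULL)
  tun <- if (with_tuning) tune_session(b, seed = child_seed(seed, "tun")) else NULL
  list(bundle = b, tm = tmb, tuning = tun)
}

# As scenario_session(), but steps through successive seeds until a session
# satisfies the structural precondition (enough balanced trials per cell) —
# the same eligibility screen the replay pipeline applies. The effect under
# test is never part of the retry decision.
scenario_session_ok <- function(seed, ..., max_tries = 6) {
  for (k in seq_len(max_tries) - 1L) {
    s <- scenario_session(seed + k, ...)
    if (!is.null(s)) return(s)
  }
  stop("no eligible session within ", max_tries, " seeds of ", seed)
}

# Balanced trial matrix with state-specific planted means: stationary trials
# drawn around `stat_means`, running trials around `run_means`
# (stimuli x neurons matrices with direction rownames and neuron colnames).
rbind_states <- function(stat_means, run_means, n_per_cell = 4, noise_sd = 0,
                         seed = 1) {
  stopifnot(identical(dim(stat_means), dim(run_means)))
  classes <- rownames(stat_means)
  set.seed(seed)
  mk <- function(means, state) {
    rows <- expand.grid(rep = seq_len(n_per_cell), class = classes,
                        stringsAsFactors = FALSE)
    resp <- means[rows$class, , drop = FALSE] +
      matrix(rnorm(nrow(rows) * ncol(means), 0, noise_sd), nrow(rows), ncol(means))
    list(resp = resp, class = rows$class, state = rep(state, nrow(rows)))
  }
  a <- mk(stat_means, "stationary")
  b <- mk(run_means, "running")
  resp <- rbind(a$resp, b$resp)
  rownames(resp) <- NULL
  colnames(resp) <- colnames(stat_means)
  trial_matrix(resp, c(a$class, b$class), c(a$state, b$state),
               source_session = "planted-states")
}
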