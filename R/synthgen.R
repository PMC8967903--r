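# Synthetic session generator: drifting-grating imaging sessions with planted
# ground truth, so every downstream stage can be tested by parameter recovery.

#' Configuration for synthetic session generation
#'
#' Bundles the study conditions emulated by [generate_session()]: a 30 Hz
#' drifting-grating session (2 s gratings, 1 s blanks, 8 directions x `n_reps`
#' repetitions) flanked by spontaneous (blank-screen) blocks, a two-state
#' running-bout speed trace, a pupil trace that covaries with speed, and
#' per-neuron activity composed of a baseline, a running-speed tuning term,
#' a direction-tuned stimulus response under a shared multiplicative trial
#' gain, slow state-dependent background noise, and white sensor noise.
#'
#' @param scenario study scenario. `"reliability_gap"` plants a drop in
#'   trial-to-trial noise during running (sd `noise_sd_stationary` ->
#'   `noise_sd_running_gap`) in a random fraction `frac_gap` of neurons, with
#'   response means unchanged. `"null"` keeps trial noise identical across
#'   states (speed tuning of mean activity remains). `"suppression"` keeps
#'   noise state-independent but, during running, scales up the preferred-
#'   direction response of positively speed-tuned neurons and scales down
#'   non-preferred responses of negatively speed-tuned neurons.
#' @param n_neurons,n_directions,n_reps session size; `n_reps` is repetitions
#'   per direction.
#' @param frame_rate imaging rate, Hz.
#' @param stim_s,blank_s grating and inter-stimulus blank durations, seconds.
#' @param spont_s total spontaneous (blank screen) time, seconds, split into a
#'   leading and a trailing block.
#' @param class_props named proportions of speed-tuning classes
#'   (`up`, `down`, `nonmono`, `untuned`); must sum to 1.
#' @param dir_kappa von Mises concentration of direction tuning.
#' @param amp_meanlog,amp_sdlog log-normal parameters of per-neuron stimulus
#'   response amplitude (dF/F units).
#' @param gain_range range of |speed-tuning modulation depth| (dF/F).
#' @param baseline resting dF/F level.
#' @param noise_sd_stationary sd of the slow trial-to-trial background noise
#'   in the stationary state (dF/F).
#' @param noise_sd_running_gap running-state noise sd for reliability-gap
#'   carrier neurons.
#' @param frac_gap fraction of neurons carrying the reliability gap.
#' @param shared_gain_sd sd of the shared multiplicative trial gain on the
#'   stimulus response.
#' @param noise_shared_frac fraction of the slow background-noise variance
#'   carried by a factor common to all neurons; the dominant source of
#'   trial-to-trial noise correlations (0 disables them).
#' @param frame_noise_sd sd of white per-frame sensor noise (dF/F).
#' @param suppression_factor multiplicative change applied in the
#'   `"suppression"` scenario (preferred response x (1 + f) for up-tuned,
#'   non-preferred x (1 - f) for down-tuned neurons, during running).
#' @param bout_params list of running-bout parameters passed to
#'   [generate_speed_trace()].
#' @param calcium_kernel_s optional exponential-decay time constant (s); if
#'   non-`NULL` the generated dF/F is convolved with this kernel. Off by
#'   default: analyses operate on dF/F directly.
#' @param region,layer metadata labels attached to the session.
#' @param tf_levels temporal-frequency labels assigned at random to gratings
#'   (carried in the stimulus table, ignored by decoding).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(scenario = c("reliability_gap", "null", "suppression"),
                         n_neurons = 100L, n_directions = 8L, n_reps = 15L,
                         frame_rate = 30, stim_s = 2, blank_s = 1, spont_s = 120,
                         class_props = c(up = 0.3, down = 0.2, nonmono = 0.1, untuned = 0.4),
                         dir_kappa = 2, amp_meanlog = log(0.2), amp_sdlog = 0.5,
                         gain_range = c(0.1, 0.25), baseline = 0.05,
                         noise_sd_stationary = 0.25, noise_sd_running_gap = 0.10,
                         frac_gap = 0.5, shared_gain_sd = 0.15,
                         noise_shared_frac = 0.2, frame_noise_sd = 0.05,
                         suppression_factor = 0.5,
                         bout_params = list(), calcium_kernel_s = NULL,
                         region = "VISp", layer = "L2/3",
                         tf_levels = c(1, 2, 4, 8, 15)) {
  scenario <- match.arg(scenario)
  stopifnot(n_neurons >= 1, n_directions >= 2, frame_rate > 0, stim_s > 0, blank_s >= 0)
  if (abs(sum(class_props) - 1) > 1e-8)
    stop("class_props must sum to 1")
  if (!all(c("up", "down", "nonmono", "untuned") %in% names(class_props)))
    stop("class_props must name up, down, nonmono, untuned")
  structure(list(
    scenario = scenario, n_neurons = as.integer(n_neurons),
    n_directions = as.integer(n_directions), n_reps = as.integer(n_reps),
    frame_rate = frame_rate, stim_s = stim_s, blank_s = blank_s, spont_s = spont_s,
    class_props = class_props, dir_kappa = dir_kappa,
    amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog, gain_range = gain_range,
    baseline = baseline, noise_sd_stationary = noise_sd_stationary,
    noise_sd_running_gap = noise_sd_running_gap, frac_gap = frac_gap,
    shared_gain_sd = shared_gain_sd, noise_shared_frac = noise_shared_frac,
    frame_noise_sd = frame_noise_sd,
    suppression_factor = suppression_factor,
    bout_params = bout_params, calcium_kernel_s = calcium_kernel_s,
    region = region, layer = layer, tf_levels = tf_levels
  ), class = "synth_config")
}

#' Draw per-neuron ground-truth parameters
#'
#' Samples the planted parameters that [generate_session()] realises: a speed-
#' tuning class per neuron, signed modulation depth, non-monotonic bump centre
#' and width, preferred direction on the stimulus wheel, stimulus response
#' amplitude, and state-dependent trial-noise standard deviations according to
#' the scenario.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (or `NULL` for the ambient RNG stream).
#' @return a data.frame with one row per neuron and attribute
#'   `shared_gain_sd`; reliability-gap carriers are marked in `rel_gap_carrier`.
#' @export
make_ground_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    n <- config$n_neurons
    cls <- sample(names(config$class_props), n, replace = TRUE, prob = config$class_props)
    gain <- runif(n, config$gain_range[1], config$gain_range[2])
    gain[cls == "down"] <- -gain[cls == "down"]
    gain[cls == "untuned"] <- 0
    dirs <- seq(0, 360 - 360 / config$n_directions, by = 360 / config$n_directions)
    carrier <- if (config$scenario == "reliability_gap")
      runif(n) < config$frac_gap else rep(FALSE, n)
    sd_stat <- rep(config$noise_sd_stationary, n)
    sd_run <- ifelse(carrier, config$noise_sd_running_gap, sd_stat)
    truth <- data.frame(
      neuron_id = sprintf("n%04d", seq_len(n)),
      neuron_class = cls,
      speed_gain = gain,
      bump_center = runif(n, 8, 18),
      bump_width = runif(n, 3, 6),
      pref_direction = sample(dirs, n, replace = TRUE),
      dir_kappa = config$dir_kappa,
      amplitude = rlnorm(n, config$amp_meanlog, config$amp_sdlog),
      noise_sd_running = sd_run,
      noise_sd_stationary = sd_stat,
      rel_gap_carrier = carrier,
      stringsAsFactors = FALSE
    )
    attr(truth, "shared_gain_sd") <- config$shared_gain_sd
    truth
  })
}

#' Generate a two-state (stationary/running) speed trace
#'
#' A per-frame Markov chain switches between a stationary state (speed 0) and
#' running bouts; within a bout, speed follows a smooth AR(1) excursion around
#' a per-bout target drawn from `speed_range`, floored at 1 cm/s.
#'
#' @param duration_frames number of frames to generate.
#' @param frame_rate imaging rate (Hz), used to convert bout durations.
#' @param bout_params list with any of `mean_run_s`, `mean_stat_s` (mean bout
#'   durations, s; default 12), `p_enter`, `p_exit` (per-frame transition
#'   probabilities, overriding the durations), `speed_range` (cm/s, default
#'   `c(5, 25)`), `ar_phi`, `ar_sd` (within-bout smoothness).
#' @param seed integer seed or `NULL`.
#' @return numeric vector of speeds (cm/s), length `duration_frames`.
#' @export
generate_speed_trace <- function(duration_frames, frame_rate = 30,
                                 bout_params = list(), seed = NULL) {
  if (length(duration_frames) != 1 || duration_frames <= 0)
    stop("duration_frames must be a positive count")
  bp <- modifyList(list(mean_run_s = 12, mean_stat_s = 12,
                        p_enter = NULL, p_exit = NULL,
                        speed_range = c(5, 25), ar_phi = 0.98, ar_sd = 0.5),
                   bout_params)
  p_enter <- if (!is.null(bp$p_enter)) bp$p_enter else 1 / (bp$mean_stat_s * frame_rate)
  p_exit <- if (!is.null(bp$p_exit)) bp$p_exit else 1 / (bp$mean_run_s * frame_rate)
  stopifnot(p_enter >= 0, p_enter <= 1, p_exit >= 0, p_exit <= 1)
  n <- as.integer(duration_frames)
  with_seed(seed, {
    # state chain started from its stationary distribution
    p_start <- if (p_enter + p_exit > 0) p_enter / (p_enter + p_exit) else 0
    running <- logical(n)
    u <- runif(n)
    running[1] <- runif(1) < p_start
    for (k in 2:max(n, 2)) {
      if (k > n) break
      running[k] <- if (running[k - 1]) u[k] >= p_exit else u[k] < p_enter
    }
    speed <- numeric(n)
    if (any(running)) {
      r <- rle(running)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (b in which(r$values)) {
        len <- r$lengths[b]
        target <- runif(1, bp$speed_range[1], bp$speed_range[2])
        eps <- rnorm(len, 0, bp$ar_sd)
        dev <- numeric(len)
        dev[1] <- rnorm(1, 0, bp$ar_sd / sqrt(1 - bp$ar_phi^2))
        if (len > 1) for (k in 2:len) dev[k] <- bp$ar_phi * dev[k - 1] + eps[k]
        speed[starts[b]:ends[b]] <- pmax(1, target + dev)
      }
    }
    speed
  })
}

# von Mises-shaped direction weight, 1 at the preferred direction.
vm_weight <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos((theta_deg - pref_deg) * pi / 180) - 1))
}

# Speed-tuning term (dF/F) for one neuron as a function of speed.
speed_term <- function(speed, class, gain, bump_center, bump_width) {
  switch(class,
    up      = gain * (1 - exp(-speed / 8)),
    down    = gain * (1 - exp(-speed / 8)),  # gain is negative for "down"
    nonmono = abs(gain) * exp(-(speed - bump_center)^2 / (2 * bump_width^2)),
    untuned = rep(0, length(speed))
  )
}

#' Generate a synthetic imaging session with planted ground truth
#'
#' Realises a [synth_config()] into a session bundle: dF/F traces (neurons x
#' frames), running-speed and pupil traces, and a stimulus epoch table with
#' 0-based inclusive-exclusive frame ranges. Per-frame activity is
#' `baseline + speed-tuning term + direction response * shared trial gain
#' * scenario state gain + slow state-dependent background noise + white
#' sensor noise`. The slow background noise is drawn once per grating epoch
#' (and per 2 s chunk outside gratings) with standard deviation set by the
#' concurrent locomotor state, so it survives averaging over the response
#' window — this is what makes trial-to-trial reliability state-dependent.
#'
#' @param config a [synth_config()].
#' @param truth optional ground-truth data.frame from [make_ground_truth()];
#'   generated internally when `NULL`.
#' @param seed integer seed or `NULL`.
#' @return a list of class `session_bundle` with elements `dff`, `speed`,
#'   `pupil`, `stim_table`, `frame_rate`, `region`, `layer`, `session_id`, and
#'   the retained `truth`.
#' @export
generate_session <- function(config, truth = NULL, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_reps < 2)
    stop("n_reps must be >= 2 (trial-to-trial reliability is undefined otherwise)")
  fr <- config$frame_rate
  stim_f <- round(config$stim_s * fr)
  blank_f <- round(config$blank_s * fr)
  spont_f <- round(config$spont_s / 2 * fr)
  n_trials <- config$n_directions * config$n_reps
  total_f <- 2L * spont_f + n_trials * (stim_f + blank_f)
  dirs <- seq(0, 360 - 360 / config$n_directions, by = 360 / config$n_directions)

  if (is.null(truth)) truth <- make_ground_truth(config, seed = if (is.null(seed)) NULL else child_seed(seed, "truth"))
  stopifnot(nrow(truth) == config$n_neurons)

  with_seed(seed, {
    # honour spec'd sub-stream layout: the truth stream was consumed above
    trial_dir <- sample(rep(dirs, config$n_reps))
    trial_tf <- sample(config$tf_levels, n_trials, replace = TRUE)

    # stimulus table (0-based, inclusive-exclusive)
    epoch <- list()
    cursor <- 0L
    if (spont_f > 0) {
      epoch[[length(epoch) + 1L]] <- data.frame(epoch_type = "spontaneous",
        start_frame = cursor, end_frame = cursor + spont_f,
        direction = NA_real_, temporal_frequency = NA_real_)
      cursor <- cursor + spont_f
    }
    for (t in seq_len(n_trials)) {
      epoch[[length(epoch) + 1L]] <- data.frame(epoch_type = "drifting_grating",
        start_frame = cursor, end_frame = cursor + stim_f,
        direction = trial_dir[t], temporal_frequency = trial_tf[t])
      cursor <- cursor + stim_f
      if (blank_f > 0) {
        epoch[[length(epoch) + 1L]] <- data.frame(epoch_type = "blank",
          start_frame = cursor, end_frame = cursor + blank_f,
          direction = NA_real_, temporal_frequency = NA_real_)
        cursor <- cursor + blank_f
      }
    }
    if (spont_f > 0) {
      epoch[[length(epoch) + 1L]] <- data.frame(epoch_type = "spontaneous",
        start_frame = cursor, end_frame = cursor + spont_f,
        direction = NA_real_, temporal_frequency = NA_real_)
      cursor <- cursor + spont_f
    }
    stim_table <- do.call(rbind, epoch)
    stopifnot(cursor == total_f)

    speed <- generate_speed_trace(total_f, fr, config$bout_params, seed = NULL)

    # pupil: monotone noisy function of smoothed speed
    sm <- roll_mean_trunc(speed, round(2 * fr))
    pupil <- pmax(0.1, 1 + 0.03 * sm + as.numeric(stats::filter(rnorm(total_f, 0, 0.05),
                                                                0.95, method = "recursive")))

    n <- config$n_neurons
    dff <- matrix(0, n, total_f)

    # speed-tuning term per neuron
    for (j in seq_len(n)) {
      dff[j, ] <- config$baseline +
        speed_term(speed, truth$neuron_class[j], truth$speed_gain[j],
                   truth$bump_center[j], truth$bump_width[j])
    }

    # stimulus responses with shared trial gain and scenario state gains
    grat <- stim_table[stim_table$epoch_type == "drifting_grating", ]
    gains <- 1 + rnorm(n_trials, 0, attr(truth, "shared_gain_sd") %||% config$shared_gain_sd)
    vm <- outer(seq_len(n), seq_len(n_trials), function(j, t)
      vm_weight(trial_dir[t], truth$pref_direction[j], truth$dir_kappa[j]))
    for (t in seq_len(n_trials)) {
      idx <- (grat$start_frame[t] + 1L):grat$end_frame[t]
      run_trial <- mean(speed[idx]) > 3
      resp <- truth$amplitude * vm[, t] * gains[t]
      if (config$scenario == "suppression" && run_trial) {
        f <- config$suppression_factor
        is_pref <- truth$pref_direction == trial_dir[t]
        up <- truth$neuron_class == "up"
        down <- truth$neuron_class == "down"
        resp <- resp * (1 + f * (up & is_pref) - f * (down & !is_pref))
      }
      dff[, idx] <- dff[, idx] + resp
    }

    # slow state-dependent background noise: one draw per grating epoch, and
    # per ~stim-length chunk elsewhere
    seg_start <- integer(0); seg_end <- integer(0)
    seg_start <- c(seg_start, grat$start_frame + 1L); seg_end <- c(seg_end, grat$end_frame)
    covered <- logical(total_f)
    for (t in seq_len(nrow(grat))) covered[(grat$start_frame[t] + 1L):grat$end_frame[t]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (b in which(!r$values)) {
      s <- starts[b]
      while (s <= ends[b]) {
        e <- min(s + stim_f - 1L, ends[b])
        seg_start <- c(seg_start, s); seg_end <- c(seg_end, e)
        s <- e + 1L
      }
    }
    ord <- order(seg_start)
    seg_start <- seg_start[ord]; seg_end <- seg_end[ord]
    cshare <- config$noise_shared_frac %||% 0
    for (s in seq_along(seg_start)) {
      idx <- seg_start[s]:seg_end[s]
      sd_vec <- if (mean(speed[idx]) > 3) truth$noise_sd_running else truth$noise_sd_stationary
      # slow background: a common factor (noise correlations) plus an
      # independent per-neuron part, variance split by noise_shared_frac
      eta <- sd_vec * (sqrt(cshare) * rnorm(1) + sqrt(1 - cshare) * rnorm(n))
      dff[, idx] <- dff[, idx] + eta
    }

    # white sensor noise
    if (config$frame_noise_sd > 0)
      dff <- dff + matrix(rnorm(n * total_f, 0, config$frame_noise_sd), n, total_f)

    # optional exponential calcium kernel
    if (!is.null(config$calcium_kernel_s)) {
      a <- exp(-1 / (config$calcium_kernel_s * fr))
      for (j in seq_len(n))
        dff[j, ] <- as.numeric(stats::filter(dff[j, ] * (1 - a), a, method = "recursive"))
    }

    rownames(dff) <- truth$neuron_id
    bundle <- structure(list(
      dff = dff, speed = speed, pupil = pupil, stim_table = stim_table,
      frame_rate = fr, region = config$region, layer = config$layer,
      session_id = sprintf("synth-%s-%s", config$scenario,
                           if (is.null(seed)) "noseed" else seed),
      truth = truth, config = config
    ), class = "session_bundle")
    validate_session_bundle(bundle)
    bundle
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle %s: %d neurons x %d frames @ %g Hz, %s/%s>\n",
              x$session_id, nrow(x$dff), ncol(x$dff), x$frame_rate, x$region, x$layer))
  tab <- table(x$stim_table$epoch_type)
  cat("  epochs:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Structural invariants of a session bundle.
validate_session_bundle <- function(b) {
  stopifnot(is.matrix(b$dff), length(b$speed) == ncol(b$dff),
            length(b$pupil) == ncol(b$dff))
  st <- b$stim_table
  stopifnot(all(st$start_frame >= 0), all(st$end_frame <= ncol(b$dff)),
            all(st$end_frame > st$start_frame))
  o <- order(st$start_frame)
  stopifnot(all(st$start_frame[o][-1] >= st$end_frame[o][-nrow(st)]))
  stopifnot(all(b$speed >= 0), all(b$pupil > 0))
  invisible(b)
}
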