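# Leaky integrate-and-fire simulation with additive membrane-voltage noise
# and Gaussian stimulus-current tuning: shows how lowering background voltage
# noise can reduce firing while raising response reliability.

#' Configuration for LIF simulations
#'
#' Membrane dynamics follow `C_m dV/dt + g_l (V - E_l) = I_app` integrated by
#' Euler's method; crossing `V_thresh` emits a spike and resets V to `E_l`.
#' Gaussian voltage noise is added at every step. Two noise conventions are
#' available: `"stationary"` (default) scales the per-step variance so that
#' `noise_var` equals the stationary variance of the free membrane-voltage
#' fluctuation (step variance `noise_var * (1 - a^2)` with
#' `a = 1 - dt * g_l / C_m`), matching how membrane noise is quantified in
#' vivo; `"per_step"` adds variance `noise_var` at every step literally.
#'
#' @param C_m membrane capacitance, pF.
#' @param g_l leak conductance, nS.
#' @param E_l resting (and reset) potential, mV.
#' @param V_thresh spike threshold, mV.
#' @param V_init initial voltage, mV.
#' @param dt Euler step, ms.
#' @param noise_var membrane-voltage noise variance, mV^2.
#' @param noise_mode `"stationary"` or `"per_step"` (see Details).
#' @param trial_ms trial duration, ms.
#' @param n_stimuli number of stimuli on the Gaussian tuning curve.
#' @param n_reps repetitions of each stimulus per run.
#' @param tuning_width width of the stimulus tuning curve, in stimulus
#'   indices.
#' @return a list of class `lif_config`.
#' @export
lif_config <- function(C_m = 490, g_l = 16, E_l = -65, V_thresh = -49,
                       V_init = -70, dt = 0.05, noise_var = 0,
                       noise_mode = c("stationary", "per_step"),
                       trial_ms = 300, n_stimuli = 15L, n_reps = 10L,
                       tuning_width = 2) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(V_thresh > E_l, dt > 0, noise_var >= 0, C_m > 0, g_l > 0,
            trial_ms > 0, n_stimuli >= 2, n_reps >= 2)
  structure(list(C_m = C_m, g_l = g_l, E_l = E_l, V_thresh = V_thresh,
                 V_init = V_init, dt = dt, noise_var = noise_var,
                 noise_mode = noise_mode, trial_ms = trial_ms,
                 n_stimuli = as.integer(n_stimuli), n_reps = as.integer(n_reps),
                 tuning_width = tuning_width),
            class = "lif_config")
}

# Per-step noise sd implied by a config.
lif_sigma_step <- function(cfg, noise_var = cfg$noise_var) {
  if (noise_var == 0) return(0)
  if (cfg$noise_mode == "per_step") return(sqrt(noise_var))
  a <- 1 - cfg$dt * cfg$g_l / cfg$C_m
  if (a <= 0 || a >= 1) stop("dt incompatible with membrane time constant")
  sqrt(noise_var * (1 - a^2))
}

#' Simulate one LIF trial
#'
#' @param cfg a [lif_config()].
#' @param current applied current in nA: a scalar (constant current) or a
#'   vector with one value per Euler step.
#' @param seed integer seed or `NULL`.
#' @param return_voltage keep the voltage trace?
#' @return list: `spike_count`, `spike_steps` (1-based step indices),
#'   `voltage` (mV per step, if requested), `rate_hz`.
#' @export
simulate_lif <- function(cfg, current, seed = NULL, return_voltage = TRUE) {
  stopifnot(inherits(cfg, "lif_config"))
  n_steps <- round(cfg$trial_ms / cfg$dt)
  if (length(current) == 1) current <- rep(current, n_steps)
  if (length(current) != n_steps)
    stop("current must be scalar or one value per step")
  res <- with_seed(seed,
    lif_sim_cpp(current * 1000, cfg$dt, cfg$C_m, cfg$g_l, cfg$E_l,
                cfg$V_thresh, cfg$V_init, lif_sigma_step(cfg), return_voltage))
  res$rate_hz <- res$spike_count / (cfg$trial_ms / 1000)
  res
}

#' Closed-form firing rate of the noiseless LIF neuron
#'
#' For constant suprathreshold current the interspike interval is
#' `T = tau * log(drive / (drive - (V_thresh - E_l)))` with `tau = C_m / g_l`
#' and `drive = I_app / g_l` (mV); the rate is `1000 / T` Hz. Subthreshold
#' currents (`drive <= V_thresh - E_l`, i.e. below rheobase
#' `g_l * (V_thresh - E_l)`) give rate 0.
#'
#' @param cfg a [lif_config()].
#' @param current_nA constant applied current, nA (vectorised).
#' @return firing rate(s) in Hz.
#' @export
lif_analytic_rate <- function(cfg, current_nA) {
  stopifnot(inherits(cfg, "lif_config"))
  drive <- 1000 * current_nA / cfg$g_l           # mV above E_l at steady state
  thr <- cfg$V_thresh - cfg$E_l
  tau <- cfg$C_m / cfg$g_l
  rate <- ifelse(drive > thr, 1000 / (tau * log(drive / (drive - thr))), 0)
  unname(rate)
}

#' Gaussian stimulus-current tuning curve
#'
#' `I(s) = peak * exp(-(s - s0)^2 / (2 width^2))` over stimulus indices
#' `1..n_stimuli`, centred at `s0 = (n_stimuli + 1) / 2` by default.
#'
#' @param peak peak current, nA.
#' @param n_stimuli number of stimuli.
#' @param width tuning width in stimulus indices.
#' @param center centre stimulus index.
#' @return vector of currents (nA), one per stimulus.
#' @export
stimulus_current_tuning <- function(peak, n_stimuli = 15, width = 2,
                                    center = (n_stimuli + 1) / 2) {
  s <- seq_len(n_stimuli)
  peak * exp(-(s - center)^2 / (2 * width^2))
}

#' Firing-rate and reliability grids over noise level and peak current
#'
#' For every (noise variance, peak current) pair, simulates `n_reps`
#' randomized presentations of each of `n_stimuli` stimuli (current levels on
#' a Gaussian tuning curve) for `trial_ms`, takes spike counts as trial
#' responses, and computes the firing rate (grid mean) and the
#' [reliability()] statistic; the whole experiment is repeated `n_runs`
#' times to get means and standard deviations.
#'
#' @param cfg a [lif_config()] (its `noise_var` field is overridden by
#'   `noise_vars`).
#' @param peak_currents peak currents to scan, nA.
#' @param noise_vars membrane noise variances to scan, mV^2.
#' @param n_runs independent repetitions of the full experiment.
#' @param seed integer seed or `NULL`.
#' @return list of class `lif_grid`: `grid` (long data.frame: noise_var,
#'   peak, run, rate_hz, reliability) and `summary` (per noise_var x peak:
#'   mean/sd of both).
#' @export
run_lif_experiment <- function(cfg = lif_config(), peak_currents = seq(0.1, 1, by = 0.1),
                               noise_vars = c(19, 36), n_runs = 10, seed = NULL) {
  stopifnot(inherits(cfg, "lif_config"))
  n_steps <- round(cfg$trial_ms / cfg$dt)
  trial_s <- cfg$trial_ms / 1000
  rows <- list()
  with_seed(seed, {
    for (nv in noise_vars) {
      sig <- lif_sigma_step(cfg, nv)
      for (pk in peak_currents) {
        I_stim <- stimulus_current_tuning(pk, cfg$n_stimuli, cfg$tuning_width)
        for (run in seq_len(n_runs)) {
          stim_seq <- sample(rep(seq_len(cfg$n_stimuli), cfg$n_reps))
          counts <- lif_counts_cpp(I_stim[stim_seq] * 1000, n_steps, cfg$dt,
                                   cfg$C_m, cfg$g_l, cfg$E_l, cfg$V_thresh,
                                   cfg$V_init, sig)
          R <- t(vapply(seq_len(cfg$n_stimuli),
                        function(s) counts[stim_seq == s], numeric(cfg$n_reps)))
          rel <- if (pop_var(as.vector(R)) == 0) NA_real_ else reliability(R)
          rows[[length(rows) + 1L]] <- data.frame(
            noise_var = nv, peak = pk, run = run,
            rate_hz = mean(counts) / trial_s, reliability = rel)
        }
      }
    }
  })
  grid <- do.call(rbind, rows)
  agg <- aggregate(cbind(rate_hz, reliability) ~ noise_var + peak, data = grid,
                   FUN = function(x) c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE)),
                   na.action = stats::na.pass)
  summary <- data.frame(noise_var = agg$noise_var, peak = agg$peak,
                        rate_mean = agg$rate_hz[, "mean"], rate_sd = agg$rate_hz[, "sd"],
                        rel_mean = agg$reliability[, "mean"], rel_sd = agg$reliability[, "sd"])
  structure(list(grid = grid, summary = summary, cfg = cfg), class = "lif_grid")
}

#' @export
print.lif_grid <- function(x, ...) {
  cat(sprintf("<lif_grid: %d noise levels x %d peaks, %d runs>\n",
              length(unique(x$summary$noise_var)), length(unique(x$summary$peak)),
              max(x$grid$run)))
  print(x$summary, digits = 3)
  invisible(x)
}
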