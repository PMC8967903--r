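---
title: "Locomotor state and visual population coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locomotor state and visual population coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`locomod` analyses how locomotion changes the way mouse visual cortex encodes
stimuli. The scientific question it operationalises is a dissociation: running
can *lower* the mean calcium activity of many extrastriate neurons while the
population as a whole becomes *easier to decode*. The package implements the
full chain of analyses needed to establish that dissociation on any session
bundle — a synthetic generator with planted ground truth, ΔF/F preprocessing,
running-speed tuning classification, state-conditioned decoding with controls,
a single-neuron reliability statistic, and a leaky integrate-and-fire (LIF)
simulation of the proposed mechanism — plus an end-to-end deterministic
`replay()`.

## The synthetic session generator

Analyses are validated by parameter recovery on synthetic sessions rather
than on archived recordings, so every downstream claim can be checked against
known ground truth. `generate_session()` emulates a standard drifting-grating
imaging session: 30 Hz traces, 8 grating directions × `n_reps` repetitions,
2 s stimulus + 1 s blank, flanking spontaneous blocks, a bout-structured
running trace, and a pupil trace that tracks smoothed speed.

Per-frame activity of neuron $j$ is

$$x_j(t) = b + f_j(v(t)) + A_j\,w_j(\theta_t)\,g_t\,s_{jt} + \eta_{j}(t) + \varepsilon_j(t)$$

where $b$ is a resting ΔF/F level (0.05), $f_j$ is the speed-tuning term
(saturating increase, saturating decrease, or an interior Gaussian bump,
by planted class), $A_j w_j(\theta_t)$ is a von Mises direction response,
$g_t \sim \mathcal N(1, 0.15^2)$ is a trial gain shared across neurons,
$s_{jt}$ is a scenario-dependent state gain, $\eta_j$ is *slow* background
noise drawn once per grating epoch (and per 2 s chunk elsewhere) with a
state-dependent standard deviation, and $\varepsilon_j$ is white sensor
noise (sd 0.05). A fraction (`noise_shared_frac`, default 0.2) of the slow
background variance is a factor common to all neurons; this common-mode
fluctuation, not the stimulus gain, is what produces measurable
trial-to-trial noise correlations (~0.2 within stimulus class) of the size
within-class shuffling is designed to remove — the multiplicative gain's
covariance contribution is orders of magnitude smaller than the background
variance at these amplitudes.

Two modelling choices matter and are deliberate:

* **The state-dependent noise is slow, not white.** A per-frame white noise
  term would be averaged away by the 2 s response window; the trial-to-trial
  variability that the reliability statistic measures must live at the trial
  timescale. We therefore hold one background draw constant across each
  grating epoch. This is what membrane-potential and network-state
  fluctuations look like at the imaging timescale.
* **The reliability-gap scenario plants its effect in half the population.**
  Carrier neurons have their trial-noise sd drop from 0.25 (stationary) to
  0.10 (running) with *no change in mean response*; non-carriers are
  state-independent. Planting the effect in a random half makes the
  exclusion controls meaningful: dropping the 50% of neurons with the most
  changed reliability should — and does — abolish the decoding gap, while
  dropping positively speed-tuned neurons should not.

Default study conditions (chosen once, as plausible values for GCaMP6f
drifting-grating data, and not revisited): 100 neurons, 15 repetitions for
quick tests and 25 for decoding-scale sessions, direction amplitudes
log-normal with median 0.2 ΔF/F, von Mises concentration κ = 2, speed
modulation depths 0.1–0.25 ΔF/F, running bouts with mean duration 12 s and
speeds 5–25 cm/s. Class proportions are 30% up, 20% down, 10% non-monotonic,
40% untuned. The `"null"` scenario keeps trial noise state-independent
(mean-activity speed tuning remains — the point of the null is that activity
changes alone do not move decoding). The `"suppression"` scenario reproduces
the population-tuning-curve signature instead: during running, up-tuned
neurons gain 50% at their preferred direction and down-tuned neurons lose
50% at non-preferred directions.

What the generator does **not** emulate: GCaMP kinetics (an optional
exponential kernel exists but analyses operate on ΔF/F directly), neuropil
contamination, motion artifacts, eye movements, or any anatomical gradient
across areas. Passing tests therefore demonstrate the *statistical machinery*
is correct and recovers planted effects; they do not certify biological
fidelity of any particular parameter value.

## Preprocessing

`compute_dff()` uses the rolling mean-of-mode baseline standard for this kind
of data: a centered rolling mode (width 5400 frames, 3 min) smoothed by a
centered rolling mean (width 3000 frames), with edge windows truncated. The
mode of a real-valued trace is defined on values binned at $10^{-3}$ of the
trace median, with ties resolved to the lowest bin so the baseline hugs the
resting level; this makes ΔF/F exactly invariant to multiplicative rescaling
of the raw fluorescence. The edge policy (truncation) and the bin resolution
are our choices — the upstream pipeline this mirrors does not publish either.

Trial responses are means over a 2 s window offset 10 frames (330 ms) from
stimulus onset; the window deliberately extends into the following blank, as
in the original design. Locomotor state is classified per trial from the
speed in the same window: running = mean > 3 cm/s and min ≥ 0.5 cm/s;
stationary = mean < 0.5 cm/s and max ≤ 3 cm/s; everything else is ambiguous
and excluded. The boundary reading is pinned by tests: "did not drop below
0.5" is inclusive (≥), "average < 0.5" is strict. `balance_trials()`
subsamples without replacement so every (direction, state) cell has exactly
the count of the smallest cell.

Sessions enter decoding only with ≥ 10 neurons and ≥ 5 balanced trials per
cell; five is our choice (no published count exists) so that 50:50 splits
retain at least two training trials per cell.

## Running-speed tuning

Tuning curves use 20 quantile bins of the covariate. Quantile (equal-
occupancy) binning is the default rather than equal-width binning because
stationary frames concentrate at speed ≈ 0; heavily tied bins are merged, so
curves can be shorter than 20 bins. Equal-width binning is available by flag.

Significance uses a permutation test built on Levene's spread idea: a tuned
neuron's curve is more variable across bins than curves computed from
activity permuted across frames. With `n_perm = 1` this is literally a
one-sided Levene t-test between the real and one shuffled curve. With
`n_perm > 1` (default 100) we rank the real curve's Levene spread statistic
(mean absolute deviation of bin means) within the permutation distribution:
$p = (1 + \#\{s_{perm} \ge s_{real}\})/(n_{perm}+1)$. We do *not* use the
median of per-permutation t-test p-values: medians of dependent p-values
concentrate near 0.5, and in our calibration runs that construction rejected
at rate 0.007 instead of 0.05. The rank-based permutation p is calibrated by
construction (measured type-I 0.045 on 1000 white-noise neurons) and the
tests pin it to [0.03, 0.07].

One honest caveat: the permutation null destroys temporal autocorrelation,
so on realistic traces (slow noise, trial structure) the test rejects
untuned neurons more often than α. The calibration claim holds for white
noise; on autocorrelated data the "fraction tuned" statistic should be read
as an upper bound. Monotonicity classes come from Spearman's ρ on the binned
curve (significantly positive / negative), with Levene-significant but
non-monotonic neurons labelled non-monotonic; α = 0.05 per neuron,
uncorrected, by design.

`fit_gaussian_speed_models()` selects among three constrained Gaussians
(centre above the speed range = increasing, below = decreasing, interior =
bump) by 10 × 75/25 cross-validation on held-out tuning curves, fitted by
bounded L-BFGS-B with argmax/quarter-range initialisation and three
restarts. Exact ties (flat curves) resolve to the interior model flagged
degenerate.

## Decoding

`fit_eval_mlr()` is an unpenalized 8-way multinomial logistic regression
(quasi-Newton fit, tight tolerance so accuracies reproduce to ≥ 3 decimals),
evaluated over ten 50:50 train/test splits. Splits are stratified within
(direction, state) cells — not stated in the original description, but
required so both state decoders see identical class balance — and the two
state decoders share each split's partition. A failed or non-converged fit
is retried with a 10⁻⁸ ridge and logged.

Controls:

* `shuffle_within_class()` permutes each neuron's responses across trials
  within each (direction, state) cell, destroying noise correlations while
  preserving every per-neuron marginal exactly (tests assert multiset
  equality). Shuffling within state as well as class is our interpretation —
  shuffling across states would destroy the state labels being compared.
  Decoders are both trained and tested on shuffled data by default.
* `exclude_neurons()` drops running-excited neurons (significant positive
  speed tuning) or the top k% of neurons by |Δ reliability|, ranked within
  session; sessions with < 10 survivors are excluded.

`compare_states()` is a two-sided Wilcoxon signed-rank test on per-session
accuracy differences. For n ≤ 25 it computes the exact null by dynamic
programming over doubled midranks, which handles tied |differences| exactly
(the off-the-shelf exact path refuses ties); above 25 it uses the normal
approximation with tie correction.

## Reliability

For a stimuli × trials response matrix, `reliability()` is the population
variance of per-stimulus mean responses divided by the population variance of
all responses. Population (not sample) variance keeps the statistic in [0, 1]
under equal trial counts. It is affine-invariant, 1 for noiseless
stimulus-dependent responses, 0 for stimulus-independent means, and for two
stimuli with means (0, 1) and unit trial noise its expectation is
0.25/1.25 = 0.2 — anchors the tests verify analytically and by Monte Carlo.
Preferred direction is the argmax of the state-pooled mean response (the
choice of pooling is ours); percent changes use the stationary mean as
baseline; the DSI null response averages the two directions orthogonal to
preferred; responsiveness is a one-way ANOVA across direction × temporal-
frequency conditions.

`population_tuning_curves()` z-scores each neuron across all trials with
states pooled *before* splitting by state (the caption-order reading of the
procedure it mirrors), sorts stimuli by pooled preference, and averages
within positively and negatively speed-tuned groups with neuron-level
bootstrap CIs.

## The LIF simulation

Membrane dynamics: $C_m \dot V + g_l (V - E_l) = I_{app}$, Euler-integrated
at dt = 0.05 ms, spike and reset to $E_l$ when $V > V_{thresh}$. Constants:
$C_m$ = 490 pF, $g_l$ = 16 nS, $E_l$ = −65 mV, $V_{thresh}$ = −49 mV,
$V_{init}$ = −70 mV. A printed value of 16 pS for the leak would give a
membrane time constant of ~30 s; we read it as 16 nS (τ ≈ 30.6 ms), which
also makes the closed-form interspike interval
$T = \tau \ln\!\big(\tfrac{I/g_l}{I/g_l - (V_{thresh}-E_l)}\big)$ come out at
≈ 22.0 ms for 0.5 nA, matching the zero-noise simulation within one Euler
step (a pinned test).

Membrane noise is Gaussian, added every step. Two conventions ship:

* `"stationary"` (default): the per-step variance is scaled by
  $(1 - a^2)$, $a = 1 - dt/\tau$, so that `noise_var` equals the stationary
  variance of the free membrane voltage — i.e. 19 and 36 mV² are the
  fluctuation levels a physiologist would measure on the trace.
* `"per_step"`: `noise_var` is injected per step literally.

The stationary calibration is the default because the literal per-step
reading at dt = 0.05 ms produces membrane fluctuations two orders of
magnitude above the quoted in-vivo levels, noise-dominated firing above
100 Hz at zero input, a reliability surface that is not monotone in noise,
and rates that change wholesale when dt changes. Under the calibrated
reading the simulation reproduces the intended physiology: rates of
0–32 Hz across the current grid, reliability rising with peak current,
reliability at 19 mV² ≥ reliability at 36 mV² at every suprathreshold
current, noise-driven firing below rheobase (0.256 nA), and < 2% rate change
when dt is halved. Stimulus drive is a Gaussian tuning curve over 15 stimuli
(width 2 stimulus indices — unspecified upstream, our default), 300 ms
trials, 10 repetitions in randomized order; reliability of spike counts uses
the same statistic as the imaging analyses. No refractory period is
modelled, and the reset target ($E_l$ = −65 mV) differs from $V_{init}$
(−70 mV) because both values are honoured literally.

## Replay, determinism, and problem sizes

`replay()` chains all stages and emits a JSON report: per-session QC,
tuning-class counts, reliability changes, accuracies per condition, paired
signed-rank p-values, the regression of the decoding gap on the session-mean
reliability change, and the LIF grid. One user seed is fanned out to every
stage via `child_seed()` (polynomial hash of a stage tag, mod 2³¹−1), so a
report is byte-identical across runs with the same seed — a pinned test.

Default replay scale is 8 sessions × 100 neurons × 8 directions × 25
repetitions; the test suite uses 6–9 sessions and 40–100 neurons, sizes at
which the full suite runs in minutes while every planted effect is
recovered with margin. Sessions whose balanced cells fall below the
eligibility rule are reported and skipped, as in the analyses this package
reproduces.

Known limitations: the tuning test's permutation null ignores
autocorrelation (above); percent-change statistics are unstable when
stationary-state means approach zero (such neurons are skipped and logged);
the session bundle's plain-text container trades storage efficiency for
portability and diffability; and the LIF model deliberately omits
recurrence, conductance synapses, and any mapping from firing rate to
calcium signal.
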