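# Single-neuron response reliability and related stimulus metrics: the
# signal-variance ratio, population tuning curves, preferred vs non-preferred
# activity changes, direction selectivity, responsiveness ANOVA, and a small
# OLS/Wald regression utility with a bootstrap envelope.

#' Trial-to-trial response reliability
#'
#' The (population) variance of a neuron's mean response across stimuli
#' divided by the (population) variance of all its single-trial responses.
#' With equal trial counts per stimulus the statistic lies in \[0, 1\]: 1 when
#' responses depend only on the stimulus (zero trial noise), 0 when the mean
#' response is identical for every stimulus.
#'
#' @param responses stimuli x trials numeric matrix (equal trials per
#'   stimulus).
#' @return a number in \[0, 1\], or `NA` (with a warning) when the total
#'   variance is zero.
#' @export
reliability <- function(responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2) stop("need at least 2 stimuli")
  if (ncol(responses) < 2) stop("need at least 2 trials per stimulus")
  if (anyNA(responses)) stop("missing responses")
  den <- pop_var(as.vector(responses))
  if (den == 0) {
    warning("zero total variance; reliability undefined")
    return(NA_real_)
  }
  pop_var(rowMeans(responses)) / den
}

# stimuli x trials response matrix for one neuron and one state from a
# balanced trial matrix.
neuron_state_matrix <- function(tm, j, state) {
  keep <- tm$state == state
  cl <- tm$class_label[keep]
  v <- tm$responses[keep, j]
  classes <- sort(unique(cl))
  t(vapply(classes, function(c) v[cl == c], numeric(sum(cl == classes[1]))))
}

#' Direction selectivity index
#'
#' `(r_pref - r_null) / (r_pref + r_null)` where `r_null` is the response to
#' the direction orthogonal to the preferred one.
#'
#' @param r_pref,r_null mean responses to the preferred and orthogonal
#'   directions.
#' @return the index, or `NA` (with a warning) when the denominator is zero.
#' @export
dsi <- function(r_pref, r_null) {
  if (r_pref + r_null == 0) {
    warning("zero denominator in DSI")
    return(NA_real_)
  }
  (r_pref - r_null) / (r_pref + r_null)
}

#' One-way ANOVA responsiveness test
#'
#' Classic one-way ANOVA of single-trial responses across stimulus conditions
#' (e.g. direction x temporal frequency). A neuron is conventionally called
#' responsive when p < 0.05.
#'
#' @param responses vector of single-trial responses.
#' @param condition parallel vector of condition labels.
#' @return the ANOVA p-value.
#' @export
responsiveness_anova <- function(responses, condition) {
  stopifnot(length(responses) == length(condition))
  g <- factor(condition)
  if (nlevels(g) < 2) stop("need at least 2 stimulus conditions")
  a <- anova(lm(responses ~ g))
  a$`Pr(>F)`[1]
}

#' Per-neuron reliability records by locomotor state
#'
#' For every neuron of a balanced trial matrix: reliability computed
#' separately on running and stationary trials, their difference, the
#' preferred direction (argmax of the state-pooled mean response), percent
#' change (running vs stationary, stationary baseline) of the mean response
#' to the preferred and to all other directions, the direction selectivity
#' index, and the responsiveness ANOVA p-value (across direction x temporal
#' frequency when temporal-frequency labels are present).
#'
#' @param tm a balanced `trial_matrix`.
#' @param zero_tol stationary means smaller than this (absolute) yield `NA`
#'   percent change for that neuron.
#' @return data.frame with one row per neuron.
#' @export
reliability_by_state <- function(tm, zero_tol = 1e-12) {
  stopifnot(inherits(tm, "trial_matrix"))
  cc <- cell_counts(tm)
  if (length(unique(as.vector(cc))) != 1)
    stop("trial matrix is not balanced; run balance_trials() first")
  ids <- colnames(tm$responses)
  classes <- sort(unique(tm$class_label))
  dirs <- suppressWarnings(as.numeric(classes))
  cond <- if (all(is.na(tm$tf))) tm$class_label else paste(tm$class_label, tm$tf)
  out <- lapply(seq_along(ids), function(j) {
    Mr <- neuron_state_matrix(tm, j, "running")
    Ms <- neuron_state_matrix(tm, j, "stationary")
    rel_r <- suppressWarnings(reliability(Mr))
    rel_s <- suppressWarnings(reliability(Ms))
    pooled <- (rowMeans(Mr) + rowMeans(Ms)) / 2
    pref_i <- which.max(pooled)
    pref_dir <- dirs[pref_i]
    # orthogonal directions (pref +/- 90 deg on the direction wheel)
    d_orth <- c((pref_dir + 90) %% 360, (pref_dir - 90) %% 360)
    orth_i <- which(dirs %in% d_orth)
    dsi_val <- if (length(orth_i) > 0)
      suppressWarnings(dsi(pooled[pref_i], mean(pooled[orth_i]))) else NA_real_
    mr_pref <- mean(Mr[pref_i, ]); ms_pref <- mean(Ms[pref_i, ])
    mr_non <- mean(Mr[-pref_i, ]); ms_non <- mean(Ms[-pref_i, ])
    pc <- function(run, stat) if (abs(stat) < zero_tol) NA_real_ else 100 * (run - stat) / stat
    data.frame(
      neuron_id = ids[j],
      rel_running = rel_r, rel_stationary = rel_s,
      delta_rel = rel_r - rel_s,
      pref_direction = pref_dir,
      pct_change_pref = pc(mr_pref, ms_pref),
      pct_change_nonpref = pc(mr_non, ms_non),
      dsi = dsi_val,
      responsive_p = responsiveness_anova(tm$responses[, j], cond),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Session-level change in preferred vs non-preferred responses
#'
#' Percent change (running vs stationary) of each neuron's mean response to
#' its preferred direction and to all other directions, averaged over the
#' included neurons of the session. Neurons with a (near-)zero stationary
#' mean are skipped with a message.
#'
#' @param tm a balanced `trial_matrix`.
#' @param include optional character vector of neuron ids to average over
#'   (e.g. neurons significantly tuned to gratings and to running); default
#'   all neurons.
#' @return list: `pct_change_pref`, `pct_change_nonpref` (session means),
#'   `per_neuron` (data.frame), `n_included`, `n_skipped`.
#' @export
pref_vs_nonpref_change <- function(tm, include = NULL) {
  rec <- reliability_by_state(tm)
  if (!is.null(include)) rec <- rec[rec$neuron_id %in% include, ]
  skip <- is.na(rec$pct_change_pref) | is.na(rec$pct_change_nonpref)
  if (any(skip))
    message(sprintf("pref_vs_nonpref_change: skipping %d neuron(s) with zero stationary mean",
                    sum(skip)))
  ok <- rec[!skip, ]
  list(pct_change_pref = mean(ok$pct_change_pref),
       pct_change_nonpref = mean(ok$pct_change_nonpref),
       per_neuron = rec, n_included = nrow(ok), n_skipped = sum(skip))
}

#' State-split population tuning curves over rank-ordered stimuli
#'
#' Each neuron's trial responses are z-scored across all trials (states
#' pooled), averaged per (stimulus, state), and the stimuli sorted by the
#' neuron's state-pooled preference (descending). Sorted curves are averaged
#' across neurons separately for positively and negatively speed-tuned
#' groups, with percentile bootstrap confidence intervals over neurons.
#'
#' @param tm a balanced `trial_matrix`.
#' @param sign_table data.frame with `neuron_id` and `tclass` (from
#'   [tune_session()]); only neurons with `tclass` `"positive"` or
#'   `"negative"` enter the curves.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed or `NULL`.
#' @return data.frame: `group`, `state`, `stim_rank`, `mean_z`, `ci_low`,
#'   `ci_high`, `n_neurons`.
#' @export
population_tuning_curves <- function(tm, sign_table, n_boot = 1000, conf = 0.95,
                                     seed = NULL) {
  stopifnot(inherits(tm, "trial_matrix"),
            all(c("neuron_id", "tclass") %in% names(sign_table)))
  ids <- colnames(tm$responses)
  classes <- sort(unique(tm$class_label))
  states <- c("running", "stationary")
  curves <- function(j) {
    v <- tm$responses[, j]
    s <- sd(v)
    if (s == 0) return(NULL)
    z <- (v - mean(v)) / s
    m <- sapply(states, function(st) vapply(classes, function(cl)
      mean(z[tm$class_label == cl & tm$state == st]), numeric(1)))
    ord <- order(rowMeans(m), decreasing = TRUE)
    m[ord, , drop = FALSE]  # stimuli (rank-ordered) x states
  }
  with_seed(seed, {
    out <- list()
    for (grp in c("positive", "negative")) {
      sel <- sign_table$neuron_id[sign_table$tclass == grp]
      jj <- which(ids %in% sel)
      mats <- Filter(Negate(is.null), lapply(jj, curves))
      if (length(mats) == 0) next
      arr <- simplify2array(mats)  # ranks x states x neurons
      mean_c <- apply(arr, c(1, 2), mean)
      boot <- array(NA_real_, c(dim(mean_c), n_boot))
      for (b in seq_len(n_boot)) {
        pick <- sample.int(length(mats), replace = TRUE)
        boot[, , b] <- apply(arr[, , pick, drop = FALSE], c(1, 2), mean)
      }
      qs <- apply(boot, c(1, 2), quantile,
                  probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      for (s in seq_along(states)) {
        out[[length(out) + 1L]] <- data.frame(
          group = grp, state = states[s], stim_rank = seq_len(nrow(mean_c)),
          mean_z = mean_c[, s], ci_low = qs[1, , s], ci_high = qs[2, , s],
          n_neurons = length(mats), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' OLS slope with Wald t test and bootstrap envelope
#'
#' Ordinary least squares of `y` on `x`, a two-sided Wald t test of the slope
#' against zero, and a percentile bootstrap envelope of the fitted line
#' (resampling (x, y) pairs).
#'
#' @param x,y numeric vectors.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level for the envelope.
#' @param grid_n number of x values in the envelope grid.
#' @param seed integer seed or `NULL`.
#' @return list: `slope`, `intercept`, `p` (Wald t, two-sided), `envelope`
#'   (data.frame x, fit, lo, hi), `n`.
#' @export
ols_wald <- function(x, y, n_boot = 1000, conf = 0.95, grid_n = 50, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) stop("predictor has no variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  grid <- seq(min(x), max(x), length.out = grid_n)
  with_seed(seed, {
    boots <- matrix(NA_real_, n_boot, grid_n)
    n <- length(x)
    for (b in seq_len(n_boot)) {
      repeat {
        id <- sample.int(n, replace = TRUE)
        if (var(x[id]) > 0) break
      }
      cb <- coef(lm(y[id] ~ x[id]))
      boots[b, ] <- cb[1] + cb[2] * grid
    }
    qs <- apply(boots, 2, quantile, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                names = FALSE)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         p = sm["x", "Pr(>|t|)"],
         envelope = data.frame(x = grid, fit = coef(fit)[1] + coef(fit)[2] * grid,
                               lo = qs[1, ], hi = qs[2, ]),
         n = length(x))
  })
}
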