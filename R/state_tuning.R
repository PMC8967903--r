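# Per-neuron behavioural-state tuning: binned tuning curves, permutation
# Levene significance, Spearman monotonicity classes, regional aggregation.

#' Binned tuning curve of activity against a behavioural covariate
#'
#' Bins the covariate into `n_bins` quantile bins (default) or equal-width
#' bins and returns the mean activity per bin. Quantile bins with heavy ties
#' (e.g. speed exactly 0 while the animal sits still) are merged with their
#' neighbours, so the curve can be shorter than `n_bins`.
#'
#' @param activity per-frame activity (dF/F).
#' @param covariate per-frame covariate (running speed cm/s, or pupil area).
#' @param n_bins requested number of bins.
#' @param binning `"quantile"` (equal-occupancy) or `"width"` (equal-width).
#' @return list with `curve` (bin means), `sem`, `bin_edges`, `bin_center`
#'   (mean covariate per bin), `n` (occupancy), `bin_index` (per-frame bin).
#' @export
speed_tuning_curve <- function(activity, covariate, n_bins = 20,
                               binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  stopifnot(length(activity) == length(covariate), n_bins >= 2)
  if (anyNA(activity) || anyNA(covariate)) stop("missing values in activity or covariate")
  br <- if (binning == "quantile")
    unique(quantile(covariate, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE))
  else
    seq(min(covariate), max(covariate), length.out = n_bins + 1)
  if (length(br) < 3)
    stop("covariate has too few distinct values to form at least 2 bins")
  idx <- findInterval(covariate, br, rightmost.closed = TRUE, all.inside = TRUE)
  k <- length(br) - 1L
  n_occ <- tabulate(idx, k)
  if (any(n_occ == 0)) {  # possible under equal-width binning
    occ <- which(n_occ > 0)
    remap <- cumsum(seq_len(k) %in% occ)
    idx <- remap[idx]
    br <- c(br[1], br[occ + 1])
    k <- length(occ)
    n_occ <- tabulate(idx, k)
  }
  sums <- rowsum(activity, idx)[, 1]
  curve <- sums / n_occ
  sq <- rowsum(activity^2, idx)[, 1]
  v <- pmax(0, sq / n_occ - curve^2)
  sem <- sqrt(v / n_occ)
  list(curve = unname(curve), sem = unname(sem), bin_edges = br,
       bin_center = unname(rowsum(covariate, idx)[, 1] / n_occ),
       n = n_occ, bin_index = idx)
}

# One-sided Levene t test between two tuning curves: is the spread (absolute
# deviation from the curve mean) of `real` larger than that of `shuf`?
levene_one_sided <- function(real, shuf) {
  a <- abs(real - mean(real))
  b <- abs(shuf - mean(shuf))
  k1 <- length(a); k2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (k1 + k2 - 2)
  if (sp2 == 0) return(if (mean(a) > mean(b)) 0 else 1)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / k1 + 1 / k2))
  pt(tstat, df = k1 + k2 - 2, lower.tail = FALSE)
}

#' Permutation Levene test for behavioural-state tuning
#'
#' Compares the real tuning curve with curves computed after permuting the
#' activity across frames (which preserves the covariate's bin structure and
#' destroys any tuning). A tuned neuron's real curve is more *spread out*
#' (Levene's statistic: mean absolute deviation of the bin means from their
#' mean) than permutation curves.
#'
#' With `n_perm = 1` the test is a single one-sided Levene t-test between the
#' real and the one shuffled curve. With `n_perm > 1` the default
#' (`perm_method = "spread"`) ranks the real curve's Levene spread within the
#' permutation distribution, `p = (1 + #\{spread_perm >= spread_real\}) /
#' (n_perm + 1)`, which is calibrated by construction under exchangeability.
#' `perm_method = "median_t"` instead reports the median of the per-
#' permutation one-sided Levene t-test p-values; note that this median
#' construction is strongly conservative (an untuned neuron rejects far less
#' often than alpha), so it is not the default.
#'
#' @inheritParams speed_tuning_curve
#' @param n_perm number of permutations (>= 1).
#' @param perm_method `"spread"` (calibrated permutation test of the Levene
#'   spread statistic) or `"median_t"` (median of pairwise Levene t-test
#'   p-values); ignored when `n_perm = 1`.
#' @param seed integer seed or `NULL`.
#' @return list with `levene_p`, `spread_real`, `spread_perm`, and the real
#'   `curve` object.
#' @export
tuning_significance <- function(activity, covariate, n_bins = 20, n_perm = 100,
                                perm_method = c("spread", "median_t"),
                                seed = NULL, binning = "quantile") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  perm_method <- match.arg(perm_method)
  tc <- speed_tuning_curve(activity, covariate, n_bins, binning)
  idx <- tc$bin_index
  occ <- tc$n
  n <- length(activity)
  lev_spread <- function(cv) mean(abs(cv - mean(cv)))
  with_seed(seed, {
    perm_curves <- vapply(seq_len(n_perm), function(j) {
      pa <- activity[sample.int(n)]
      rowsum(pa, idx)[, 1] / occ
    }, numeric(length(tc$curve)))
    perm_curves <- matrix(perm_curves, nrow = length(tc$curve))
    if (n_perm == 1) {
      p <- levene_one_sided(tc$curve, perm_curves[, 1])
    } else if (perm_method == "spread") {
      sp <- apply(perm_curves, 2, lev_spread)
      p <- (1 + sum(sp >= lev_spread(tc$curve))) / (n_perm + 1)
    } else {
      p <- median(apply(perm_curves, 2, function(sc) levene_one_sided(tc$curve, sc)))
    }
    list(levene_p = p, spread_real = lev_spread(tc$curve),
         spread_perm = apply(perm_curves, 2, lev_spread), curve = tc)
  })
}

#' Classify a neuron's behavioural-state tuning
#'
#' Monotonic classes come from the Spearman correlation of the binned tuning
#' curve with the covariate: significantly positive rho is `"positive"`,
#' significantly negative is `"negative"`. Neurons without significant
#' monotonic correlation but with a significant Levene test are
#' `"nonmonotonic"`; the remainder are `"untuned"`.
#'
#' @param levene_p permutation Levene p-value.
#' @param spearman_rho,spearman_p Spearman correlation of the binned curve
#'   with the covariate bin centres, and its p-value.
#' @param alpha significance level.
#' @return one of `"positive"`, `"negative"`, `"nonmonotonic"`, `"untuned"`.
#' @export
classify_tuning <- function(levene_p, spearman_rho, spearman_p, alpha = 0.05) {
  stopifnot(is.finite(levene_p), levene_p >= 0, levene_p <= 1,
            is.finite(spearman_p), spearman_p >= 0, spearman_p <= 1,
            is.finite(spearman_rho), abs(spearman_rho) <= 1 + 1e-12)
  if (spearman_p < alpha && spearman_rho > 0) return("positive")
  if (spearman_p < alpha && spearman_rho < 0) return("negative")
  if (levene_p < alpha) return("nonmonotonic")
  "untuned"
}

# Frames belonging to a context of the session: "stimulus" = drifting-grating
# epochs, "spontaneous" = blank-screen blocks. Inter-stimulus blanks belong to
# neither.
context_frames <- function(bundle, context = c("stimulus", "spontaneous")) {
  context <- match.arg(context)
  type <- if (context == "stimulus") "drifting_grating" else "spontaneous"
  ep <- bundle$stim_table[bundle$stim_table$epoch_type == type, ]
  if (nrow(ep) == 0) stop(sprintf("no %s epochs in session", context))
  unlist(lapply(seq_len(nrow(ep)), function(i) (ep$start_frame[i] + 1L):ep$end_frame[i]))
}

#' Behavioural-state tuning for every neuron of a session
#'
#' Runs the binned-curve / permutation-Levene / Spearman pipeline on each
#' neuron, against running speed or pupil area, restricted to stimulus or
#' spontaneous frames (inter-stimulus blanks are excluded from both).
#'
#' @param bundle a `session_bundle`.
#' @param covariate `"speed"` or `"pupil"`.
#' @param context `"stimulus"` or `"spontaneous"`.
#' @param n_bins,n_perm,alpha,binning tuning-test parameters.
#' @param seed integer seed or `NULL`.
#' @return data.frame, one row per neuron: `neuron_id`, `levene_p`,
#'   `spearman_rho`, `spearman_p`, `tclass`, plus session metadata.
#' @export
tune_session <- function(bundle, covariate = c("speed", "pupil"),
                         context = c("stimulus", "spontaneous"),
                         n_bins = 20, n_perm = 100, alpha = 0.05,
                         binning = "quantile", seed = NULL) {
  covariate <- match.arg(covariate)
  context <- match.arg(context)
  frames <- context_frames(bundle, context)
  cov <- (if (covariate == "speed") bundle$speed else bundle$pupil)[frames]
  n <- nrow(bundle$dff)
  res <- vector("list", n)
  for (j in seq_len(n)) {
    act <- bundle$dff[j, frames]
    sig <- tuning_significance(act, cov, n_bins, n_perm,
                               seed = if (is.null(seed)) NULL else child_seed(seed, paste0("n", j)),
                               binning = binning)
    ct <- suppressWarnings(cor.test(sig$curve$bin_center, sig$curve$curve,
                                    method = "spearman"))
    res[[j]] <- data.frame(
      neuron_id = rownames(bundle$dff)[j],
      levene_p = sig$levene_p,
      spearman_rho = unname(ct$estimate),
      spearman_p = ct$p.value,
      tclass = classify_tuning(sig$levene_p, unname(ct$estimate), ct$p.value, alpha),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$covariate <- covariate
  out$context <- context
  out$region <- bundle$region
  out$layer <- bundle$layer
  out$session_id <- bundle$session_id
  out
}

#' Session inclusion rule for speed-tuning analyses
#'
#' A session is included if the animal ran for at least `min_run_frac` of the
#' stimulus-presentation frames (frame counted as running when speed exceeds
#' `run_frame_thresh`) and reached a maximum speed of at least
#' `min_max_speed` cm/s.
#'
#' @param bundle a `session_bundle`.
#' @param min_run_frac minimum running fraction of stimulus frames.
#' @param min_max_speed minimum peak speed (cm/s).
#' @param run_frame_thresh frame-level running threshold (cm/s).
#' @return logical; attributes `run_frac` and `max_speed` carry the measured
#'   quantities.
#' @export
session_qc <- function(bundle, min_run_frac = 0.25, min_max_speed = 15,
                       run_frame_thresh = 1) {
  frames <- context_frames(bundle, "stimulus")
  run_frac <- mean(bundle$speed[frames] > run_frame_thresh)
  max_speed <- max(bundle$speed)
  structure(run_frac >= min_run_frac && max_speed >= min_max_speed,
            run_frac = run_frac, max_speed = max_speed)
}

#' Aggregate tuning results by region and layer
#'
#' For each region x layer group: the fraction of neurons with a significant
#' Levene test, and the mean Spearman rho among monotonically tuned neurons
#' with a percentile bootstrap confidence interval.
#'
#' @param results data.frame as returned by [tune_session()] (possibly
#'   row-bound across sessions).
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level.
#' @param alpha significance level for "tuned".
#' @param seed integer seed or `NULL`.
#' @return data.frame with one row per region x layer.
#' @export
aggregate_region <- function(results, n_boot = 1000, conf = 0.95, alpha = 0.05,
                             seed = NULL) {
  stopifnot(all(c("region", "layer", "levene_p", "spearman_rho", "tclass") %in% names(results)))
  groups <- unique(results[, c("region", "layer")])
  with_seed(seed, {
    out <- lapply(seq_len(nrow(groups)), function(g) {
      sub <- results[results$region == groups$region[g] & results$layer == groups$layer[g], ]
      mono <- sub[sub$tclass %in% c("positive", "negative"), ]
      if (nrow(mono) > 0) {
        mean_rho <- mean(mono$spearman_rho)
        bm <- vapply(seq_len(n_boot), function(b)
          mean(mono$spearman_rho[sample.int(nrow(mono), replace = TRUE)]), numeric(1))
        ci <- quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      } else {
        mean_rho <- NA_real_; ci <- c(NA_real_, NA_real_)
      }
      data.frame(region = groups$region[g], layer = groups$layer[g],
                 n_neurons = nrow(sub),
                 fraction_tuned = mean(sub$levene_p < alpha),
                 n_monotonic = nrow(mono),
                 mean_rho_monotonic = mean_rho,
                 ci_low = ci[1], ci_high = ci[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
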