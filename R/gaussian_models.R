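# Constrained Gaussian models of speed-tuning curves: monotonically
# increasing (centre above the observed speed range), monotonically
# decreasing (centre below it), and interior-peaked, selected by
# cross-validated error on held-out tuning curves.

gauss_pred <- function(p, x) p[4] + p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))

fit_one_gauss <- function(x, y, c_lo, c_hi, seed_jitter = 0) {
  r <- max(x) - min(x)
  amp0 <- diff(range(y))
  init <- c(amp = if (amp0 > 0) amp0 else 1e-3,
            center = min(max(x[which.max(y)], c_lo), c_hi),
            width = r / 4, offset = min(y))
  # amplitude is constrained non-negative: the monotone models encode their
  # direction through the centre placement, and a negative-amplitude Gaussian
  # with an out-of-range centre would mimic the opposite monotone shape
  lower <- c(0, c_lo, r / 50, min(y) - 2 * (amp0 + 1e-6))
  upper <- c(2 * max(abs(y), 1e-6) + 1e-6, c_hi, 5 * r, max(y) + 2 * (amp0 + 1e-6))
  obj <- function(p) sum((gauss_pred(p, x) - y)^2)
  best <- NULL
  for (s in 0:2) {
    ini <- init
    if (s > 0) {
      jit <- c(0.5, 0.25 * r, 0.5, 0) * (s == 1) + c(-0.5, -0.25 * r, 1, 0) * (s == 2)
      ini <- pmin(pmax(init * c(1 + jit[1], 1, 1 + jit[3], 1) + c(0, jit[2], 0, 0), lower), upper)
    }
    fit <- tryCatch(optim(ini, obj, method = "L-BFGS-B", lower = lower, upper = upper),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  best
}

#' Select a constrained Gaussian model of speed tuning by cross-validation
#'
#' For each of `n_cv` random 75/25 frame splits, tuning curves are built
#' separately on the training and test frames; three Gaussians — centre
#' constrained above the speed range (increasing), below it (decreasing), or
#' inside it (interior peak) — are least-squares fitted to the training curve
#' and scored by squared error against the test curve. The model with the
#' lowest mean cross-validated error wins; exact ties (including flat curves,
#' where all models collapse to an offset) resolve to `"interior"` with the
#' fit flagged degenerate.
#'
#' @inheritParams speed_tuning_curve
#' @param n_cv number of cross-validation repetitions.
#' @param train_frac fraction of frames in the training split.
#' @param seed integer seed or `NULL`.
#' @return list of class `gaussian_model_fit`: `model`, `params` (amplitude,
#'   center, width, offset), `cv_error`, per-model `cv_table`, `degenerate`.
#' @export
fit_gaussian_speed_models <- function(activity, covariate, n_cv = 10,
                                      train_frac = 0.75, n_bins = 20,
                                      binning = "quantile", seed = NULL) {
  stopifnot(length(activity) == length(covariate), n_cv >= 1,
            train_frac > 0, train_frac < 1)
  n <- length(activity)
  lo <- min(covariate); hi <- max(covariate); r <- hi - lo
  bounds <- list(increasing = c(hi, hi + 3 * r),
                 decreasing = c(lo - 3 * r, lo),
                 interior   = c(lo + 1e-9 * max(r, 1), hi - 1e-9 * max(r, 1)))
  errs <- matrix(NA_real_, n_cv, 3, dimnames = list(NULL, names(bounds)))
  with_seed(seed, {
    for (cv in seq_len(n_cv)) {
      tr <- sample.int(n, round(train_frac * n))
      te <- setdiff(seq_len(n), tr)
      ctr <- speed_tuning_curve(activity[tr], covariate[tr], n_bins, binning)
      cte <- speed_tuning_curve(activity[te], covariate[te], n_bins, binning)
      for (m in seq_along(bounds)) {
        fit <- fit_one_gauss(ctr$bin_center, ctr$curve,
                             bounds[[m]][1], bounds[[m]][2])
        errs[cv, m] <- if (is.null(fit)) Inf
          else mean((gauss_pred(fit$par, cte$bin_center) - cte$curve)^2)
      }
    }
    cv_err <- colMeans(errs)
    degenerate <- FALSE
    best <- which.min(cv_err)
    if (sum(abs(cv_err - min(cv_err)) < 1e-12) > 1) {  # exact tie
      best <- which(names(bounds) == "interior")
      degenerate <- TRUE
    }
    full <- speed_tuning_curve(activity, covariate, n_bins, binning)
    fit <- fit_one_gauss(full$bin_center, full$curve,
                         bounds[[best]][1], bounds[[best]][2])
    if (sd(full$curve) < 1e-12) degenerate <- TRUE
    params <- if (is.null(fit)) c(amp = 0, center = mean(covariate),
                                  width = r / 4, offset = mean(activity))
              else fit$par
    structure(list(model = names(bounds)[best],
                   params = c(amplitude = unname(params[1]), center = unname(params[2]),
                              width = unname(params[3]), offset = unname(params[4])),
                   cv_error = unname(cv_err[best]), cv_table = cv_err,
                   degenerate = degenerate),
              class = "gaussian_model_fit")
  })
}
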