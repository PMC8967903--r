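# State-conditioned stimulus decoding: unpenalized multinomial logistic
# regression over cross-validated splits, with trial-shuffling and
# neuron-exclusion controls, and a paired signed-rank comparison of states.

fit_multinom <- function(X, y, decay = 0) {
  df <- data.frame(X, check.names = FALSE)
  df$.y <- factor(y)
  nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500,
                 reltol = 1e-10, decay = decay,
                 MaxNWts = (ncol(X) + 2) * nlevels(df$.y) + 8)
}

#' Cross-validated state-conditioned stimulus decoding
#'
#' For each of `n_splits` random splits, trials are partitioned 50:50 into
#' train and test, stratified within every (direction, state) cell so both
#' state decoders see the same class balance. An unpenalized 8-way
#' multinomial logistic regression is fitted per locomotor state on that
#' state's training trials and scored on its held-out trials; accuracies are
#' averaged over splits. Fits that fail or do not converge are retried with a
#' tiny ridge penalty (1e-8) and a message.
#'
#' @param tm a balanced `trial_matrix` (see [balance_trials()]).
#' @param n_splits number of train/test splits.
#' @param train_frac fraction of each cell assigned to training (by count,
#'   rounded down).
#' @param seed integer seed or `NULL`.
#' @param condition optional list of flags recorded in the result (e.g.
#'   `list(shuffled = TRUE, exclusion = "running_positive")`).
#' @return list of class `decoding_result`: `accuracy_running`,
#'   `accuracy_stationary`, `per_split` (n_splits x 2 matrix), `condition`,
#'   `session_id`.
#' @export
fit_eval_mlr <- function(tm, n_splits = 10, train_frac = 0.5, seed = NULL,
                         condition = list()) {
  stopifnot(inherits(tm, "trial_matrix"))
  cc <- cell_counts(tm)
  if (any(tm$state == "ambiguous")) stop("trial matrix contains ambiguous-state trials")
  if (length(unique(as.vector(cc))) != 1)
    stop("trial matrix is not balanced; run balance_trials() first")
  n_cell <- cc[1, 1]
  if (floor(n_cell * train_frac) < 2 || n_cell - floor(n_cell * train_frac) < 1)
    stop("too few trials per (class, state) cell for a 50:50 split")
  classes <- sort(unique(tm$class_label))
  states <- c("running", "stationary")
  acc <- matrix(NA_real_, n_splits, 2, dimnames = list(NULL, states))
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      train <- logical(length(tm$state))
      for (cl in classes) for (st in states) {
        rows <- which(tm$class_label == cl & tm$state == st)
        train[rows[sample.int(length(rows), floor(length(rows) * train_frac))]] <- TRUE
      }
      for (st in states) {
        tr <- train & tm$state == st
        te <- !train & tm$state == st
        # standardize by training statistics: an affine reparameterization
        # that leaves the unregularized MLR optimum unchanged but makes the
        # fit well-conditioned and exactly invariant to per-neuron rescaling
        mu <- colMeans(tm$responses[tr, , drop = FALSE])
        sg <- apply(tm$responses[tr, , drop = FALSE], 2, sd)
        sg[sg == 0] <- 1
        Xtr <- sweep(sweep(tm$responses[tr, , drop = FALSE], 2, mu), 2, sg, `/`)
        Xte <- sweep(sweep(tm$responses[te, , drop = FALSE], 2, mu), 2, sg, `/`)
        fit <- tryCatch(fit_multinom(Xtr, tm$class_label[tr]),
                        error = function(e) NULL)
        if (is.null(fit) || isTRUE(fit$convergence > 0)) {
          message("fit_eval_mlr: refitting with tiny ridge (1e-8)")
          fit <- fit_multinom(Xtr, tm$class_label[tr], decay = 1e-8)
        }
        pred <- predict(fit, newdata = data.frame(Xte, check.names = FALSE))
        acc[s, st] <- mean(as.character(pred) == tm$class_label[te])
      }
    }
  })
  structure(list(accuracy_running = mean(acc[, "running"]),
                 accuracy_stationary = mean(acc[, "stationary"]),
                 per_split = acc,
                 condition = modifyList(list(shuffled = FALSE, exclusion = "none",
                                             k_percent = NULL), condition),
                 session_id = tm$source_session),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result %s: running %.3f, stationary %.3f (%s%s)>\n",
              x$session_id, x$accuracy_running, x$accuracy_stationary,
              if (x$condition$shuffled) "shuffled, " else "",
              x$condition$exclusion))
  invisible(x)
}

#' Shuffle responses across trials within (class, state) cells
#'
#' Independently for every neuron and every (direction, state) cell, permutes
#' that neuron's responses across the cell's trials. Class and state labels
#' are untouched, so all per-neuron marginal statistics are preserved exactly
#' while trial-to-trial co-fluctuations (noise correlations) between neurons
#' are destroyed.
#'
#' @param tm a `trial_matrix`.
#' @param seed integer seed or `NULL`.
#' @return a `trial_matrix` with shuffled responses.
#' @export
shuffle_within_class <- function(tm, seed = NULL) {
  stopifnot(inherits(tm, "trial_matrix"))
  resp <- tm$responses
  cells <- split(seq_len(nrow(resp)),
                 list(class = tm$class_label, state = tm$state), drop = TRUE)
  with_seed(seed, {
    for (rows in cells) {
      if (length(rows) < 2) next
      for (j in seq_len(ncol(resp)))
        resp[rows, j] <- resp[rows[sample.int(length(rows))], j]
    }
  })
  trial_matrix(resp, tm$class_label, tm$state, tm$tf, tm$window_s,
               tm$offset_frames, tm$source_session)
}

#' Exclude neurons from a trial matrix by tuning or reliability
#'
#' `"running_positive"` drops neurons classified as significantly positively
#' speed-tuned (`tclass == "positive"` in `aux`, a [tune_session()] table).
#' `"reliability_top_k"` ranks neurons by |delta reliability| (running minus
#' stationary, from `aux`, a [reliability_by_state()] table) and drops the
#' top `k_percent` percent.
#'
#' @param tm a `trial_matrix` with neuron ids as response column names.
#' @param rule exclusion rule.
#' @param aux auxiliary per-neuron table covering all neurons in `tm`.
#' @param k_percent percent of neurons to drop (reliability rule).
#' @param min_neurons minimum surviving neurons (session excluded otherwise).
#' @return a `trial_matrix` with the surviving neuron columns.
#' @export
exclude_neurons <- function(tm, rule = c("running_positive", "reliability_top_k"),
                            aux, k_percent = NULL, min_neurons = 10) {
  rule <- match.arg(rule)
  ids <- colnames(tm$responses)
  stopifnot(!is.null(ids), all(ids %in% aux$neuron_id))
  aux <- aux[match(ids, aux$neuron_id), ]
  drop <- if (rule == "running_positive") {
    aux$tclass == "positive"
  } else {
    if (is.null(k_percent)) stop("k_percent required for reliability_top_k")
    n_drop <- floor(length(ids) * k_percent / 100)
    rank_idx <- order(abs(aux$delta_rel), decreasing = TRUE)
    seq_along(ids) %in% rank_idx[seq_len(n_drop)]
  }
  if (sum(!drop) < min_neurons)
    stop(sprintf("only %d neurons survive exclusion (minimum %d); session excluded",
                 sum(!drop), min_neurons))
  trial_matrix(tm$responses[, !drop, drop = FALSE], tm$class_label, tm$state,
               tm$tf, tm$window_s, tm$offset_frames, tm$source_session)
}

# Exact null distribution of the signed-rank statistic with midranks (ties
# allowed): dynamic programming over doubled ranks.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  W2 <- sum(r2[d > 0])
  S <- sum(r2)
  f <- numeric(S + 1)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(S + 1)] <- g[(r + 1):(S + 1)] + f[1:(S + 1 - r)]
    f <- g
  }
  f <- f / 2^n
  p_ge <- sum(f[(W2 + 1):(S + 1)])
  p_le <- sum(f[1:(W2 + 1)])
  min(1, 2 * min(p_ge, p_le))
}

#' Paired comparison of running vs stationary decoding accuracy
#'
#' Two-sided Wilcoxon signed-rank test on per-session accuracy differences
#' (running minus stationary). For n <= 25 pairs the exact tied-rank null
#' distribution is used (computed by dynamic programming, so tied |differences|
#' are handled exactly); larger samples use the normal approximation with tie
#' correction. Zero differences are discarded; if all differences are zero the
#' result is flagged degenerate with p = 1.
#'
#' @param results list of `decoding_result` objects, or a data.frame with
#'   columns `accuracy_running` and `accuracy_stationary`.
#' @return list: `statistic` (W+, sum of positive signed ranks), `p`, `n`
#'   (non-zero pairs), `mean_diff`, `degenerate`.
#' @export
compare_states <- function(results) {
  if (is.data.frame(results)) {
    d <- results$accuracy_running - results$accuracy_stationary
  } else {
    d <- vapply(results, function(r) r$accuracy_running - r$accuracy_stationary,
                numeric(1))
  }
  if (length(d) < 6) stop("need at least 6 paired sessions")
  mean_diff <- mean(d)
  dz <- d[d != 0]
  if (length(dz) == 0)
    return(list(statistic = 0, p = 1, n = 0L, mean_diff = mean_diff, degenerate = TRUE))
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  n <- length(dz)
  p <- if (n <= 25) {
    signed_rank_exact_p(dz)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p = p, n = as.integer(n), mean_diff = mean_diff,
       degenerate = FALSE)
}
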