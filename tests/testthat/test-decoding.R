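dirs8 <- as.character(seq(0, 315, by = 45))

test_that("linearly separable classes decode perfectly in both states", {
  means <- diag(8) * 5
  rownames(means) <- dirs8
  colnames(means) <- sprintf("n%02d", 1:8)
  tm <- make_planted_tm(means, n_per_cell = 6, noise_sd = 0.01, seed = 2)
  res <- fit_eval_mlr(tm, seed = 3)
  expect_equal(res$accuracy_running, 1)
  expect_equal(res$accuracy_stationary, 1)
  expect_equal(dim(res$per_split), c(10, 2))
  expect_true(all(res$per_split >= 0 & res$per_split <= 1))
})

test_that("decoder accuracy is invariant to per-neuron affine rescaling", {
  means <- diag(8) * 3
  rownames(means) <- dirs8
  colnames(means) <- sprintf("n%02d", 1:8)
  tm <- make_planted_tm(means, n_per_cell = 6, noise_sd = 0.5, seed = 4)
  tm2 <- tm
  scales <- seq(0.5, 4, length.out = 8)
  shifts <- seq(-2, 2, length.out = 8)
  tm2$responses <- sweep(sweep(tm$responses, 2, scales, `*`), 2, shifts, `+`)
  r1 <- fit_eval_mlr(tm, seed = 5)
  r2 <- fit_eval_mlr(tm2, seed = 5)
  expect_equal(r1$per_split, r2$per_split)
  expect_equal(r1$accuracy_running, r2$accuracy_running)
  expect_equal(r1$accuracy_stationary, r2$accuracy_stationary)
})

test_that("label-permuted decoding sits at 8-way chance", {
  # average over two sessions and 20 splits so the estimate's Monte-Carlo
  # error is well inside the chance band
  accs <- c()
  for (base in c(61, 71)) {
    s <- scenario_session_ok(base, with_tuning = FALSE, min_cell = 4)
    tm <- s$tm
    set.seed(6 + base)
    for (st in c("running", "stationary")) {
      i <- tm$state == st
      tm$class_label[i] <- sample(tm$class_label[i])
    }
    res <- fit_eval_mlr(tm, n_splits = 20, seed = 7 + base)
    accs <- c(accs, res$accuracy_running, res$accuracy_stationary)
  }
  chance <- mean(accs)
  expect_gt(chance, 0.09)
  expect_lt(chance, 0.16)
})

test_that("running accuracy exceeds stationary on reliability-gap sessions", {
  # first 10 sessions (scanning seeds) that pass the eligibility screen
  gaps <- c()
  seed <- 700
  while (length(gaps) < 10 && seed < 740) {
    seed <- seed + 1
    s <- scenario_session(seed, with_tuning = FALSE, min_cell = 5)
    if (is.null(s)) next
    r <- fit_eval_mlr(s$tm, seed = child_seed(seed, "mlr"))
    gaps <- c(gaps, r$accuracy_running - r$accuracy_stationary)
  }
  expect_length(gaps, 10)
  expect_gte(mean(gaps > 0), 0.9)
})

test_that("within-class shuffling preserves marginals and kills correlations", {
  s <- scenario_session_ok(62, with_tuning = FALSE, min_cell = 5)
  tm <- s$tm
  shuf <- shuffle_within_class(tm, seed = 8)
  # per-neuron per-cell response multisets are exactly preserved
  cells <- split(seq_along(tm$class_label), list(tm$class_label, tm$state), drop = TRUE)
  for (rows in cells) {
    expect_equal(apply(shuf$responses[rows, , drop = FALSE], 2, sort),
                 apply(tm$responses[rows, , drop = FALSE], 2, sort))
  }
  # labels untouched
  expect_identical(shuf$class_label, tm$class_label)
  expect_identical(shuf$state, tm$state)
  # planted common-noise correlations vanish
  expect_gt(mean_within_cell_corr(tm), 0.1)
  expect_lt(abs(mean_within_cell_corr(shuf)), 0.03)
})

test_that("shuffling single-trial cells is the identity", {
  means <- diag(2)
  rownames(means) <- c("0", "90")
  colnames(means) <- c("a", "b")
  tm <- make_planted_tm(means, n_per_cell = 1, noise_sd = 1, seed = 9)
  shuf <- shuffle_within_class(tm, seed = 10)
  expect_identical(shuf$responses, tm$responses)
})

test_that("neuron exclusion rules drop the right columns and guard the floor", {
  means <- matrix(rnorm(8 * 40), 8, 40, dimnames = list(dirs8, sprintf("n%02d", 1:40)))
  tm <- make_planted_tm(means, n_per_cell = 4, noise_sd = 0.2, seed = 11)
  aux_none <- data.frame(neuron_id = colnames(tm$responses), tclass = "untuned")
  expect_identical(exclude_neurons(tm, "running_positive", aux_none)$responses,
                   tm$responses)
  aux_some <- aux_none
  aux_some$tclass[1:5] <- "positive"
  kept <- exclude_neurons(tm, "running_positive", aux_some)
  expect_equal(ncol(kept$responses), 35)
  expect_false(any(aux_some$neuron_id[1:5] %in% colnames(kept$responses)))
  # reliability rule: k = 50 on 40 neurons leaves 20, the least-changed ones
  aux_rel <- data.frame(neuron_id = colnames(tm$responses),
                        delta_rel = seq(-1, 1, length.out = 40))
  kept50 <- exclude_neurons(tm, "reliability_top_k", aux_rel, k_percent = 50)
  expect_equal(ncol(kept50$responses), 20)
  expect_true(all(abs(aux_rel$delta_rel[match(colnames(kept50$responses),
                                              aux_rel$neuron_id)]) <= 0.5 + 1e-9))
  aux_pos <- aux_none
  aux_pos$tclass <- "positive"
  aux_pos$tclass[1:5] <- "untuned"
  expect_error(exclude_neurons(tm, "running_positive", aux_pos), "survive")
})

test_that("the paired signed-rank comparison matches exact enumeration", {
  # all-positive constant shift, n = 10: two-sided exact p = 2 / 2^10
  shifted <- data.frame(accuracy_running = seq(0.5, 0.59, by = 0.01) + 0.1,
                        accuracy_stationary = seq(0.5, 0.59, by = 0.01))
  cs <- compare_states(shifted)
  expect_equal(cs$p, 2 / 1024, tolerance = 1e-12)
  expect_equal(cs$statistic, 55)
  # identical accuracies are degenerate with p = 1
  same <- data.frame(accuracy_running = rep(0.5, 8), accuracy_stationary = rep(0.5, 8))
  cs0 <- compare_states(same)
  expect_true(cs0$degenerate)
  expect_equal(cs0$p, 1)
  # antisymmetric differences are far from significant
  anti <- data.frame(accuracy_running = 0.5 + c(0.1, -0.1, 0.2, -0.2, 0.15, -0.15),
                     accuracy_stationary = rep(0.5, 6))
  expect_gt(compare_states(anti)$p, 0.5)
  expect_error(compare_states(same[1:4, ]), "at least 6")
})

test_that("the exact tied-rank null agrees with wilcox.test on tie-free data", {
  set.seed(12)
  for (rep in 1:5) {
    d <- round(rnorm(12), 6)
    while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(12), 6)
    df <- data.frame(accuracy_running = 0.5 + d, accuracy_stationary = rep(0.5, 12))
    ours <- compare_states(df)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})
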