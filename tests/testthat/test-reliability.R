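test_that("reliability hits its analytic anchors", {
  # noiseless stimulus-dependent responses: all variance is signal
  expect_equal(reliability(rbind(c(1, 1, 1), c(2, 2, 2))), 1)
  # stimulus-independent means: no signal variance
  expect_equal(reliability(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_error(reliability(matrix(1:3, 1)), "2 stimuli")
  expect_error(reliability(matrix(1:2, 2, 1)), "2 trials")
  expect_warning(r0 <- reliability(matrix(5, 3, 4)), "zero total variance")
  expect_true(is.na(r0))
})

test_that("reliability matches the law-of-total-variance expectation", {
  # two stimuli with means 0 and 1, within-stimulus sd 1:
  # expected value var(means) / (var(means) + sigma^2) = 0.25 / 1.25 = 0.2
  set.seed(13)
  Tn <- 20000
  R <- rbind(rnorm(Tn, 0, 1), rnorm(Tn, 1, 1))
  expect_equal(reliability(R), 0.2, tolerance = 0.015)
})

test_that("reliability is affine-invariant and monotone in trial noise", {
  set.seed(14)
  R <- rbind(rnorm(500, 0, 1), rnorm(500, 2, 1), rnorm(500, 4, 1))
  expect_equal(reliability(3.7 * R - 11), reliability(R), tolerance = 1e-12)
  # fixed means, shrinking noise raises reliability (law-of-total-variance grid)
  means <- c(0, 1, 2)
  rels <- sapply(c(2, 1, 0.5, 0.25), function(s) {
    set.seed(15)
    reliability(means + matrix(rnorm(3 * 4000, 0, s), 3, 4000))
  })
  expect_true(all(diff(rels) > 0))
})

test_that("DSI follows its defining ratio", {
  expect_equal(dsi(2, 1), 1 / 3)
  expect_equal(dsi(4, 4), 0)
  expect_equal(dsi(3, 0), 1)
  expect_warning(d0 <- dsi(1, -1), "denominator")
  expect_true(is.na(d0))
})

test_that("responsiveness ANOVA detects shifts and is calibrated under the null", {
  set.seed(16)
  # one condition shifted by 10 sd: overwhelming evidence
  y <- c(rnorm(40), rnorm(40, 10), rnorm(40))
  g <- rep(c("a", "b", "c"), each = 40)
  p <- responsiveness_anova(y, g)
  expect_lt(p, 1e-6)
  # cross-check against the F-distribution oracle
  ref <- oneway.test(y ~ factor(g), var.equal = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-12)
  expect_error(responsiveness_anova(rnorm(10), rep("a", 10)), "2 stimulus conditions")
  # null p-values are uniform (Kolmogorov-Smirnov)
  ps <- replicate(400, responsiveness_anova(rnorm(30), rep(c("a", "b", "c"), each = 10)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("per-neuron reliability records separate planted state noise", {
  s <- scenario_session(63, with_tuning = FALSE, min_cell = 3)
  expect_false(is.null(s))
  rec <- reliability_by_state(s$tm)
  expect_equal(nrow(rec), ncol(s$tm$responses))
  expect_true(all(rec$delta_rel == rec$rel_running - rec$rel_stationary))
  ok <- !is.na(rec$rel_running) & !is.na(rec$rel_stationary)
  expect_true(all(rec$rel_running[ok] >= 0 & rec$rel_running[ok] <= 1))
  expect_true(all(rec$pref_direction %in% seq(0, 315, by = 45)))
})

test_that("preferred vs non-preferred change recovers planted gain structure", {
  dirs <- as.character(seq(0, 315, by = 45))
  base <- matrix(0.2, 8, 5, dimnames = list(dirs, sprintf("n%d", 1:5)))
  base["90", ] <- 1  # every neuron prefers 90 degrees
  # running doubles the preferred response only
  up <- base
  up["90", ] <- 2
  tm1 <- rbind_states(base, up)
  r1 <- suppressWarnings(pref_vs_nonpref_change(tm1))
  expect_equal(r1$pct_change_pref, 100, tolerance = 1e-9)
  expect_equal(r1$pct_change_nonpref, 0, tolerance = 1e-9)
  # running halves the non-preferred responses only
  down <- base
  down[rownames(down) != "90", ] <- 0.1
  tm2 <- rbind_states(base, down)
  r2 <- suppressWarnings(pref_vs_nonpref_change(tm2))
  expect_equal(r2$pct_change_pref, 0, tolerance = 1e-9)
  expect_equal(r2$pct_change_nonpref, -50, tolerance = 1e-9)
  # no state effect at all
  r3 <- suppressWarnings(pref_vs_nonpref_change(rbind_states(base, base)))
  expect_equal(r3$pct_change_pref, 0)
  expect_equal(r3$pct_change_nonpref, 0)
})

test_that("population tuning curves z-score, sort, and split by state", {
  dirs <- as.character(seq(0, 315, by = 45))
  # symmetric neuron, identical in both states: curves must coincide
  m <- matrix(seq(0.8, 0.1, length.out = 8), 8, 1, dimnames = list(dirs, "n1"))
  tm <- rbind_states(m, m, n_per_cell = 5, noise_sd = 0.02, seed = 17)
  sign_tab <- data.frame(neuron_id = "n1", tclass = "positive")
  pc <- population_tuning_curves(tm, sign_tab, n_boot = 100, seed = 18)
  run <- pc$mean_z[pc$state == "running"]
  stat <- pc$mean_z[pc$state == "stationary"]
  expect_equal(run, stat, tolerance = 0.1)
  expect_true(all(diff((run + stat) / 2) <= 0.1))  # sorted by preference
  # pooled z-scores average to ~0 across sorted stimuli
  expect_lt(abs(mean(pc$mean_z)), 0.05)
})

test_that("the suppression scenario lowers running curves at non-preferred ranks", {
  s <- scenario_session(64, scenario = "suppression", min_cell = 3)
  expect_false(is.null(s))
  pc <- population_tuning_curves(s$tm, s$tuning, n_boot = 200,
                                 seed = child_seed(64, "ptc"))
  neg <- pc[pc$group == "negative", ]
  expect_gt(nrow(neg), 0)
  gap_at <- function(r) neg$mean_z[neg$state == "stationary" & neg$stim_rank == r] -
    neg$mean_z[neg$state == "running" & neg$stim_rank == r]
  # the running deficit is concentrated at the least-preferred stimuli
  expect_gt(gap_at(8), 0)
  expect_gt(gap_at(8), gap_at(1))
  pos <- pc[pc$group == "positive", ]
  if (nrow(pos) > 0) {
    boost <- pos$mean_z[pos$state == "running" & pos$stim_rank == 1] -
      pos$mean_z[pos$state == "stationary" & pos$stim_rank == 1]
    expect_gt(boost, 0)
  }
})

test_that("OLS Wald regression recovers exact lines and rejects flat predictors", {
  x <- seq(1, 18)
  fit <- suppressWarnings(ols_wald(x, 2 * x, n_boot = 200, seed = 19))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_lt(fit$p, 1e-12)
  expect_true(all(fit$envelope$lo <= fit$envelope$fit + 1e-9 &
                  fit$envelope$fit <= fit$envelope$hi + 1e-9))
  expect_error(ols_wald(rep(3, 18), rnorm(18)), "no variance")
  # null calibration at n = 18
  set.seed(20)
  rej <- mean(replicate(400, ols_wald(rnorm(18), rnorm(18), n_boot = 2)$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
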