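test_that("tuning curves track the covariate and flatten for constant activity", {
  set.seed(1)
  cov <- runif(2000, 0, 30)
  tc <- speed_tuning_curve(cov, cov)
  expect_length(tc$curve, 20)
  expect_true(all(diff(tc$curve) > 0))
  expect_equal(unname(suppressWarnings(
    cor.test(tc$bin_center, tc$curve, method = "spearman"))$estimate), 1)
  flat <- speed_tuning_curve(rep(7, 2000), cov)
  expect_true(all(flat$curve == 7))
  # anti-correlated activity with vanishing noise gives rho -> -1 (rank oracle)
  tc2 <- speed_tuning_curve(-cov + rnorm(2000, 0, 1e-8), cov)
  expect_equal(unname(suppressWarnings(
    cor.test(tc2$bin_center, tc2$curve, method = "spearman"))$estimate), -1)
})

test_that("quantile bins are equal-occupancy for distinct covariate values", {
  set.seed(2)
  tc <- speed_tuning_curve(rnorm(1999), runif(1999))
  expect_lte(diff(range(tc$n)), 1)
  # heavy ties merge bins rather than erroring
  cov <- c(rep(0, 1500), runif(500, 1, 20))
  tc2 <- speed_tuning_curve(rnorm(2000), cov)
  expect_lt(length(tc2$curve), 20)
  expect_gte(length(tc2$curve), 2)
})

test_that("the permutation Levene test detects tuning and respects degenerate input", {
  set.seed(3)
  cov <- runif(3000, 0, 30)
  sig <- tuning_significance(0.05 * cov + rnorm(3000, 0, 0.05), cov, seed = 4)
  expect_lt(sig$levene_p, 0.05)
  # constant activity has zero curve spread: never significant
  sig0 <- tuning_significance(rep(2, 3000), cov, seed = 5)
  expect_gte(sig0$levene_p, 0.99)
  sig1 <- tuning_significance(rep(2, 3000), cov, n_perm = 1, seed = 6)
  expect_equal(sig1$levene_p, 1)
  expect_error(tuning_significance(rnorm(100), runif(100), n_perm = 0), "n_perm")
})

test_that("tuning classification implements the decision table totally and exclusively", {
  expect_equal(classify_tuning(0.001, 0.9, 0.001), "positive")
  expect_equal(classify_tuning(0.001, -0.9, 0.001), "negative")
  expect_equal(classify_tuning(0.001, 0.1, 0.4), "nonmonotonic")
  expect_equal(classify_tuning(0.5, 0.0, 0.9), "untuned")
  set.seed(7)
  for (i in 1:200) {
    cl <- classify_tuning(runif(1), runif(1, -1, 1), runif(1))
    expect_true(cl %in% c("positive", "negative", "nonmonotonic", "untuned"))
  }
})

test_that("constrained Gaussian model selection recovers planted shapes", {
  set.seed(9)
  cov <- runif(4000, 0, 30)
  # interior bump
  bump <- 0.5 * exp(-(cov - 14)^2 / (2 * 4^2)) + rnorm(4000, 0, 0.05)
  fit <- fit_gaussian_speed_models(bump, cov, seed = 10)
  expect_equal(fit$model, "interior")
  bw <- 30 / 20
  expect_lt(abs(fit$params["center"] - 14), bw + 0.5)
  # generate-and-recover from the model class itself: a rising flank of a
  # Gaussian whose centre lies above the covariate range
  up <- 0.5 * exp(-(cov - 40)^2 / (2 * 15^2)) + rnorm(4000, 0, 0.03)
  fit2 <- fit_gaussian_speed_models(up, cov, seed = 11)
  expect_equal(fit2$model, "increasing")
  # and a falling flank with the centre below it
  dn <- 0.5 * exp(-(cov + 10)^2 / (2 * 15^2)) + rnorm(4000, 0, 0.03)
  fit3 <- fit_gaussian_speed_models(dn, cov, seed = 12)
  expect_equal(fit3$model, "decreasing")
  # flat activity: degenerate tie resolved toward interior
  flat <- fit_gaussian_speed_models(rep(1, 4000), cov, seed = 13)
  expect_equal(flat$model, "interior")
  expect_true(flat$degenerate)
})

test_that("session QC applies the running-fraction and peak-speed rules", {
  st <- make_stim_table(rep(0, 10))
  n <- max(st$end_frame)
  dff <- matrix(0, 1, n)
  mk_speed <- function(frac_run, peak) {
    s <- rep(0, n)
    k <- round(frac_run * n)
    if (k > 0) s[1:k] <- peak
    s
  }
  expect_false(as.logical(session_qc(make_bundle(dff, mk_speed(0, 0), st))))
  expect_true(as.logical(session_qc(make_bundle(dff, mk_speed(0.3, 20), st))))
  expect_false(as.logical(session_qc(make_bundle(dff, mk_speed(0.3, 10), st))))
  expect_false(as.logical(session_qc(make_bundle(dff, mk_speed(0.1, 20), st))))
})

test_that("regional aggregation averages monotonic rho with bootstrap CIs", {
  mk <- function(rho, tclass, n) data.frame(
    region = "VISp", layer = "L2/3", neuron_id = sprintf("x%d", seq_len(n)),
    levene_p = 0.01, spearman_rho = rho, spearman_p = 0.01, tclass = tclass)
  agg <- aggregate_region(mk(0.5, "positive", 30), seed = 1)
  expect_equal(agg$mean_rho_monotonic, 0.5)
  expect_equal(agg$ci_low, 0.5)
  expect_equal(agg$ci_high, 0.5)
  expect_equal(agg$fraction_tuned, 1)
  mixed <- rbind(mk(0.4, "positive", 20), mk(-0.4, "negative", 20))
  agg2 <- aggregate_region(mixed, seed = 2)
  expect_equal(agg2$mean_rho_monotonic, 0, tolerance = 1e-12)
  expect_lt(agg2$ci_low, 0); expect_gt(agg2$ci_high, 0)
})

test_that("a down-tuned region is recovered with negative mean rho", {
  cfg <- synth_config(scenario = "null", n_neurons = 60, n_reps = 15,
                      class_props = c(up = 0.1, down = 0.7, nonmono = 0, untuned = 0.2),
                      gain_range = c(0.3, 0.5), noise_sd_stationary = 0.08,
                      frame_noise_sd = 0.03, shared_gain_sd = 0,
                      amp_meanlog = log(0.05), region = "VISam")
  b <- generate_session(cfg, seed = 17)
  tun <- tune_session(b, seed = 18, n_perm = 50)
  agg <- aggregate_region(tun, seed = 19)
  expect_lt(agg$mean_rho_monotonic, 0)
  expect_lt(agg$ci_high, 0)
  expect_gt(agg$fraction_tuned, 0.5)
})

test_that("pupil and speed covariates run through the same path", {
  cfg <- synth_config(n_neurons = 6, n_reps = 4, spont_s = 30)
  b <- generate_session(cfg, seed = 23)
  for (cv in c("speed", "pupil")) {
    tun <- tune_session(b, cv, "spontaneous", n_perm = 20, seed = 24)
    expect_equal(nrow(tun), 6)
    expect_identical(unique(tun$covariate), cv)
    expect_true(all(tun$tclass %in% c("positive", "negative", "nonmonotonic", "untuned")))
  }
})
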