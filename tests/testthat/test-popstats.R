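test_that("classifier false-positive rate on log-normal data matches the normal tail", {
  set.seed(101)
  n <- 1e6
  x <- rlnorm(n, meanlog = 0, sdlog = 0.4)
  thr <- accumulator_threshold(x)
  fp <- mean(x > thr)
  p <- pnorm(-3)                       # 0.00135
  mc_se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(fp - p), 3 * mc_se)
})

test_that("degenerate and bimodal steady-state samples are handled explicitly", {
  expect_error(accumulator_threshold(rep(1, 100)), "at least 500")
  same <- rep(2, 1000)
  expect_equal(accumulator_threshold(same), 2)     # sigma = 0
  expect_equal(accumulator_threshold(same, domain = "linear"), 2)
  set.seed(3)
  bimix <- c(rlnorm(2000, 0, 0.2), rlnorm(800, log(40), 0.2))
  expect_warning(accumulator_threshold(bimix), "bimodal")
})

test_that("fraction series locates the transient maximum", {
  times <- 0:5
  samples <- list(rep(1, 10), rep(1, 10), c(rep(1, 6), rep(50, 4)),
                  c(rep(1, 8), rep(50, 2)), rep(1, 10), rep(1, 10))
  res <- accumulator_fraction_series(samples, times, threshold_rpu = 10)
  expect_equal(res$max_fraction, 0.4)
  expect_equal(res$max_time_h, 2)
  expect_equal(res$fraction_series$fraction[1], 0)
  inf_res <- accumulator_fraction_series(samples, times, Inf)
  expect_true(all(inf_res$fraction_series$fraction == 0))
})

test_that("GMM split recovers a well-separated mixture and its weight", {
  set.seed(42)
  x <- c(rlnorm(1400, 0, 0.25), rlnorm(600, log(10^1.5), 0.25))
  sp <- split_subpopulations_gmm(x)
  expect_true(sp$bimodal)
  w_upper <- length(sp$accumulator) / length(x)
  expect_equal(w_upper, 0.3, tolerance = 0.02 / 0.3)
  expect_gt(median(sp$accumulator) / median(sp$non_accumulator), 10)
})

test_that("monomodal samples are declared monomodal by the GMM split", {
  set.seed(7)
  x <- rlnorm(2000, 0, 0.3)
  sp <- split_subpopulations_gmm(x)
  expect_false(sp$bimodal)
  expect_equal(length(sp$non_accumulator), length(x))
  expect_equal(length(sp$accumulator), 0L)
  expect_error(split_subpopulations_gmm(rlnorm(100)), "at least 500")
})

test_that("GMM split on a simulator burnout snapshot finds the >= 10x mode", {
  cfg <- scenario_config("scfv", n_cells = 2000L, seed = 4)
  sim <- simulate_population(cfg, step_profile(1), 8)
  # bimodality is maximal a few hours after induction (t = 3 h dark + 3.5 h)
  snap <- sim$snapshots[[which.min(abs(sim$times - 6.75))]]
  x <- snap$trf[snap$strain == "interest" & snap$trf > 0]
  sp <- split_subpopulations_gmm(x)
  expect_true(sp$bimodal)
  expect_gte(median(sp$accumulator) / median(sp$non_accumulator), 10)
})

test_that("GMM and threshold classifier agree on well-separated data", {
  cfg <- scenario_config("scfv", n_cells = 2000L, seed = 4)
  sim <- simulate_population(cfg, step_profile(1), 27)
  last <- sim$snapshots[[length(sim$times)]]
  thr <- accumulator_threshold(
    last$trf[last$strain == "interest" & last$trf > 0])
  snap <- sim$snapshots[[which.min(abs(sim$times - 6.75))]]
  x <- snap$trf[snap$strain == "interest" & snap$trf > 0]
  frac_thr <- mean(x > thr)
  sp <- split_subpopulations_gmm(x)
  frac_gmm <- length(sp$accumulator) / length(x)
  expect_lt(abs(frac_thr - frac_gmm), 0.05)
})

test_that("induction threshold interpolates the 5-point net increase", {
  curve <- data.frame(induction = c(0, 0.3, 0.6, 1.0),
                      max_fraction = c(0.01, 0.01, 0.06, 0.40))
  res <- induction_threshold(curve)
  expect_equal(res$basal_fraction, 0.01)
  expect_equal(res$induction_threshold, 0.6)  # basal+0.05 reached exactly there
  # crossing strictly between measured points is interpolated
  curve2 <- data.frame(induction = c(0, 0.3, 0.6, 1.0),
                       max_fraction = c(0.01, 0.01, 0.11, 0.40))
  # target 0.06 crossed between 0.3 (0.01) and 0.6 (0.11): halfway
  expect_equal(induction_threshold(curve2)$induction_threshold, 0.45)
  # the definition is a net increase, not an absolute level
  curve3 <- data.frame(induction = c(0, 0.5, 1),
                       max_fraction = c(0.50, 0.50, 0.56))
  res3 <- induction_threshold(curve3)
  # crossing of 0.55 between 0.5 and 1: (0.55-0.50)/(0.56-0.50) of the way
  expect_equal(res3$induction_threshold, 0.5 + 0.5 * 5 / 6)
  expect_warning(res4 <- induction_threshold(
    data.frame(induction = c(0, 0.5, 1), max_fraction = c(0.01, 0.01, 0.02))),
    "never rises")
  expect_true(is.na(res4$induction_threshold))
  expect_error(induction_threshold(curve[1:2, ]), "at least 3")
})

test_that("target stress level is the same crossing on the stress axis", {
  curve <- data.frame(mean_upr = c(0.1, 0.2, 0.26, 0.4),
                      max_fraction = c(0.01, 0.03, 0.06, 0.3))
  res <- target_stress_level(curve)
  expect_equal(res$target_stress_rpu, 0.26)
  curve2 <- data.frame(mean_upr = c(0.1, 0.2, 0.3),
                       max_fraction = c(0.02, 0.02, 0.025))
  expect_warning(res2 <- target_stress_level(curve2), "never rises")
  expect_true(is.na(res2$target_stress_rpu))
})

test_that("growth inference is exact on noise-free exponential co-cultures", {
  t <- seq(0, 8, by = 0.75)
  mu_a <- 0.4
  # interest growing at 0.25/h: log-odds slope = mu_a - mu_i = 0.15
  L0 <- log(0.1 / 0.9)
  f_a <- plogis(L0 + (mu_a - 0.25) * t)
  res <- infer_growth_rate(data.frame(time_h = t, f_a = f_a), mu_a)
  expect_lt(max(abs(res$growth_rate - 0.25)), 1e-6)
  # equal growth: constant fraction, inferred rate equals the accessory's
  res2 <- infer_growth_rate(data.frame(time_h = t, f_a = rep(0.09, length(t))),
                            mu_a)
  expect_true(all(res2$growth_rate == mu_a))
})

test_that("growth inference flags saturated fractions and short series", {
  t <- 0:5
  f <- c(0.1, 0.2, 1, 0.4, 0.5, 0.6)
  expect_warning(res <- infer_growth_rate(data.frame(time_h = t, f_a = f), 0.4),
                 "touches 0 or 1")
  expect_equal(nrow(res), 3L)  # 5 usable points -> 3 interior estimates
  expect_error(suppressWarnings(infer_growth_rate(
    data.frame(time_h = 0:1, f_a = c(0.1, 0.2)), 0.4)), "at least 3")
})

test_that("co-culture growth inference recovers the pre-induction rate end to end", {
  cfg <- small_cfg(n_cells = 2000L, events_per_sample = 5000L)
  sim <- simulate_experiment(cfg, constant_induction(0, from = 0), 8)
  proc <- suppressWarnings(process_events(sim$events, induction_start_h = 8))
  s <- proc$summaries
  res <- infer_growth_rate(
    data.frame(time_h = s$time_h, f_a = 1 - s$fraction_interest), cfg$mu0)
  expect_lt(abs(mean(res$growth_rate) - 0.4), 0.05)
})

test_that("burnout depresses the inferred growth rate by >= 30% at the wave peak", {
  cfg <- scenario_config("scfv", n_cells = 2000L, seed = 4,
                         events_per_sample = 5000L)
  sim <- simulate_experiment(cfg, step_profile(1), 12)
  proc <- process_events(sim$events, induction_start_h = 3)
  s <- proc$summaries
  res <- infer_growth_rate(
    data.frame(time_h = s$time_h, f_a = 1 - s$fraction_interest), cfg$mu0)
  expect_lte(min(res$growth_rate) / cfg$mu0, 0.7)
  # the dip coincides with the accumulator wave (within the smoothing window)
  t_dip <- res$time_h[which.min(res$growth_rate)]
  expect_gt(t_dip, 3); expect_lt(t_dip, 9)
})
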