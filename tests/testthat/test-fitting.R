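test_that("reporter-stage fit recovers rates on noise-free data within 1%", {
  rs <- reporter_series(noise_cv = 0, seed = 1)
  fit <- fit_reporter_stage(rs$series, induction = 1, seed = 1)
  expect_equal(fit$params$Kprd, rs$truth$Kprd, tolerance = 0.01)
  expect_equal(fit$params$Kdil, rs$truth$Kdil, tolerance = 0.01)
  expect_equal(fit$params$Ktrf, rs$truth$Ktrf, tolerance = 0.01)
  expect_true(fit$converged)
  ts <- reporter_timescales(fit)
  expect_equal(unname(ts["generation_time_min"]), 90, tolerance = 0.01)
  expect_equal(unname(ts["prd_halflife_min"]), 20, tolerance = 0.01)
})

test_that("reporter-stage fit recovers the 90-min generation time at default noise", {
  # the estimator is stochastic at 5% noise; check the median over seeds
  gt <- vapply(1:5, function(s) {
    rs <- reporter_series(seed = s)
    fit <- fit_reporter_stage(rs$series, induction = 1, seed = s)
    reporter_timescales(fit)[["generation_time_min"]]
  }, numeric(1L))
  expect_lt(abs(median(gt) - 90) / 90, 0.10)
})

test_that("degenerate reporter series are rejected", {
  flat <- data.frame(time_h = seq(0, 24, 0.75), value = 0)
  expect_error(fit_reporter_stage(flat, 1), "non-identifiable")
  short <- data.frame(time_h = seq(0, 3, 0.75), value = 1:5)
  expect_error(fit_reporter_stage(short, 1), ">= 6 h")
})

test_that("unit-scale calibration is an exact linear ratio", {
  p <- model_params(Kprd = 2, Ktrf = 1.2, Ksec = 0.4, Kdeg = 0.1, Kdil = 0.46)
  traj <- simulate_ode(p, constant_induction(1, from = 0), c(0, 12, 24))
  sec24 <- traj$Sec[traj$time_h == 24]
  expect_equal(calibrate_units(2 * sec24, p, induction = 1), 2, tolerance = 1e-8)
  expect_equal(calibrate_units(sec24, p, induction = 1), 1, tolerance = 1e-8)
  expect_error(calibrate_units(-1, p, 1), "positive")
  p0 <- model_params(Kprd = 2, Ktrf = 1.2, Ksec = 0, Kdeg = 0.1, Kdil = 0.46)
  expect_error(calibrate_units(1, p0, 1), "Ksec")
})

make_poi_data <- function(truth, induction, noise_cv = 0.02, seed = 5) {
  times <- seq(0, 24, by = 0.75)
  traj <- simulate_ode(truth, constant_induction(induction, from = 0), times)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  list(series = data.frame(
         time_h = times,
         value = traj$Trf * rlnorm(length(times), -sdlog^2 / 2, sdlog)),
       sec24 = traj$Sec[times == 24] * rlnorm(1, -sdlog^2 / 2, sdlog))
}

fixed_stage1 <- list(Kprd = 2.079, Kdil = 0.462, Kunits = 2.5)

test_that("per-induction fit recovers trafficking rates within 15% at 2% noise", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0.5, Kdeg = 0.2,
                        Kdil = 0.462, Kunits = 2.5)
  d <- make_poi_data(truth, induction = 0.8)
  fit <- fit_per_induction(d$series, d$sec24, fixed_stage1, induction = 0.8,
                           seed = 3)
  expect_lt(abs(fit$params$Ktrf - truth$Ktrf) / truth$Ktrf, 0.15)
  expect_lt(abs(fit$params$Ksec - truth$Ksec) / truth$Ksec, 0.15)
  expect_lt(abs(fit$params$Kdeg - truth$Kdeg) / truth$Kdeg, 0.15)
})

test_that("zero secretion endpoint drives Ksec to zero with Kdeg absorbing outflux", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0, Kdeg = 0.7,
                        Kdil = 0.462, Kunits = 2.5)
  d <- make_poi_data(truth, induction = 1, noise_cv = 0)
  fit <- fit_per_induction(d$series, 0, fixed_stage1, induction = 1, seed = 2)
  expect_lt(fit$params$Ksec, 0.02)
  expect_equal(fit$params$Kdeg, 0.7, tolerance = 0.1)
})

test_that("fits are invariant to induction rescaling of model-generated data", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0.5, Kdeg = 0.2,
                        Kdil = 0.462, Kunits = 2.5)
  d1 <- make_poi_data(truth, induction = 0.4, noise_cv = 0)
  d2 <- make_poi_data(truth, induction = 0.8, noise_cv = 0)
  f1 <- fit_per_induction(d1$series, d1$sec24, fixed_stage1, 0.4, seed = 4)
  f2 <- fit_per_induction(d2$series, d2$sec24, fixed_stage1, 0.8, seed = 4)
  for (k in c("Ktrf", "Ksec", "Kdeg"))
    expect_equal(f1$params[[k]], f2$params[[k]], tolerance = 0.02)
})

test_that("fits are stable under time-grid refinement of the same trajectory", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0.5, Kdeg = 0.2,
                        Kdil = 0.462, Kunits = 2.5)
  coarse_t <- seq(0, 24, by = 1.5)
  fine_t <- seq(0, 24, by = 0.375)
  mk <- function(times) {
    traj <- simulate_ode(truth, constant_induction(0.8, from = 0), times)
    data.frame(time_h = times, value = traj$Trf)
  }
  sec24 <- simulate_ode(truth, constant_induction(0.8, from = 0),
                        c(0, 24))$Sec[2]
  fc <- fit_per_induction(mk(coarse_t), sec24, fixed_stage1, 0.8, seed = 6)
  ff <- fit_per_induction(mk(fine_t), sec24, fixed_stage1, 0.8, seed = 6)
  for (k in c("Ktrf", "Ksec", "Kdeg"))
    expect_lt(abs(fc$params[[k]] - ff$params[[k]]) / ff$params[[k]], 0.02)
})

test_that("missing endpoint is flagged non-identifiable but still fits the series", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0.5, Kdeg = 0.2,
                        Kdil = 0.462, Kunits = 2.5)
  d <- make_poi_data(truth, induction = 0.8, noise_cv = 0)
  expect_warning(
    fit <- fit_per_induction(d$series, NA, fixed_stage1, 0.8, seed = 2),
    "non-identifiable")
  expect_false(fit$identifiable)
  # the outflux sum is still constrained by the series
  expect_equal(fit$params$Ksec + fit$params$Kdeg, 0.7, tolerance = 0.05)
})

test_that("CMA-ES best-so-far objective is non-increasing and minimizes test functions", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r <- cma_es(rosen, c(-1.2, 1), sigma0 = 0.5, max_iter = 400, seed = 2)
  expect_lt(r$value, 1e-8)
  expect_equal(r$par, c(1, 1), tolerance = 1e-3)
  expect_true(all(diff(r$history) <= 0))
  r2 <- cma_es(function(x) sum((x - 3)^2), rep(0, 5), sigma0 = 1, seed = 9)
  expect_equal(r2$par, rep(3, 5), tolerance = 1e-4)
})

test_that("parameter_trend sorts by induction and guards edge cases", {
  truth <- model_params(Kprd = 2.079, Ktrf = 1.4, Ksec = 0.5, Kdeg = 0.2,
                        Kdil = 0.462, Kunits = 2.5)
  fits <- lapply(c(0.8, 0.4), function(ind) {
    d <- make_poi_data(truth, ind, noise_cv = 0)
    fit_per_induction(d$series, d$sec24, fixed_stage1, ind, seed = 1)
  })
  tab <- parameter_trend(fits)
  expect_equal(tab$induction, c(0.4, 0.8))
  # constant generating params across inductions -> flat trends
  expect_equal(tab$Ktrf[1], tab$Ktrf[2], tolerance = 0.02)
  expect_error(parameter_trend(list()), "no fits")
  expect_warning(parameter_trend(fits[c(1, 1)]), "duplicate")
})
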