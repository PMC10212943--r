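raw_events <- function(n = 10, time_h = 0, FSC = 1500, GRN_B = 300,
                       BLU_V = 10, ORG_G = 50) {
  data.frame(time_h = time_h, reactor_id = "R1", FSC = FSC, SSC = 400,
             GRN_B = GRN_B, BLU_V = BLU_V, ORG_G = ORG_G)[rep(1, n), ]
}

test_that("channel correction multiplies only the named channels", {
  ev <- raw_events()
  same <- apply_channel_correction(ev, c(GRN_B = 1, BLU_V = 1, ORG_G = 1))
  expect_equal(same, ev)
  up <- apply_channel_correction(ev, c(GRN_B = 2, BLU_V = 1, ORG_G = 1))
  expect_equal(up$GRN_B, ev$GRN_B * 2)
  expect_equal(up$BLU_V, ev$BLU_V)
  # round trip with reciprocal coefficients
  back <- apply_channel_correction(up, c(GRN_B = 0.5, BLU_V = 1, ORG_G = 1))
  expect_equal(back$GRN_B, ev$GRN_B, tolerance = 1e-12)
  expect_error(apply_channel_correction(ev, c(GRN_B = 0, BLU_V = 1, ORG_G = 1)),
               "positive")
  expect_warning(apply_channel_correction(ev, c(GRN_B = 2)), "defaulting to 1")
})

test_that("FSC gate keeps the closed interval [1000, 2000]", {
  ev <- raw_events(5)
  ev$FSC <- c(500, 1000, 1500, 2000, 2500)
  kept <- gate_cells(ev)
  expect_equal(kept$FSC, c(1000, 1500, 2000))  # boundaries inclusive
  # uniform FSC in [0, 3000]: about a third survives
  set.seed(8)
  u <- raw_events(30000)
  u$FSC <- runif(30000, 0, 3000)
  expect_equal(nrow(gate_cells(u)) / 30000, 1 / 3, tolerance = 0.02)
  expect_warning(gate_cells(raw_events(3, FSC = 10)), "all events")
})

test_that("RPU conversion is size and reference normalization", {
  ev <- raw_events(1, FSC = 1500, GRN_B = 300)
  refs <- c(GRN_B = 0.2, BLU_V = 0.2, ORG_G = 0.2)
  rpu <- to_rpu(ev, refs)
  expect_equal(rpu$GRN_B, 300 / 1500 / 0.2)  # = 1 RPU
  expect_error(to_rpu(rpu, refs), "never silently re-processed")
  expect_error(to_rpu(ev, c(GRN_B = 0.2)), "must provide")
})

test_that("baseline subtraction maps the pre-induction window to zero mean", {
  set.seed(2)
  ev <- raw_events(4000, time_h = rep(c(1.5, 2.25, 3, 3.75), each = 1000))
  ev$GRN_B <- rnorm(4000, 30, 3)
  ev$BLU_V <- rnorm(4000, 2, 0.2)   # all strain-of-interest (low marker)
  ev$ORG_G <- rnorm(4000, 15, 2)
  rpu <- to_rpu(ev, default_rpu_references(), induction_start_h = 3)
  pre <- rpu$time_h < 3
  expect_equal(mean(rpu$GRN_B[pre]), 0, tolerance = 1e-10)
  expect_equal(mean(rpu$ORG_G[pre]), 0, tolerance = 1e-10)
  # negative values after subtraction are preserved
  expect_gt(sum(rpu$GRN_B < 0), 0)
  expect_error(to_rpu(raw_events(5, time_h = 10), default_rpu_references(),
                      induction_start_h = 3), "baseline")
})

test_that("strain split uses the BLU-V thresholds with an excluded dead band", {
  ev <- raw_events(3)
  ev$BLU_V <- c(0.01, 0.10, 0.045) * ev$FSC * 100 / 1450  # raw-domain setup
  rpu <- to_rpu(ev, default_rpu_references())
  parts <- split_strains(rpu)
  expect_equal(nrow(parts$interest), 1L)
  expect_equal(nrow(parts$accessory), 1L)
  expect_equal(nrow(parts$unclassified), 1L)
  expect_equal(parts$interest$BLU_V, 0.01, tolerance = 1e-10)
  expect_error(split_strains(raw_events(2)), "to_rpu")
})

test_that("counts are conserved across the split", {
  cfg <- small_cfg(events_per_sample = 3000L)
  sim <- simulate_population(cfg, step_profile(0.4), 6)
  ev <- emulate_cytometry(sim$snapshots[[7]], cfg, time_h = 4.5, seed = 13)
  gated <- gate_cells(ev)
  parts <- split_strains(to_rpu(gated, default_rpu_references()))
  expect_identical(nrow(parts$interest) + nrow(parts$accessory) +
                     nrow(parts$unclassified), nrow(gated))
})

test_that("the full chain recovers strain fractions and contents from the simulator", {
  cfg <- small_cfg(n_cells = 1500L, events_per_sample = 5000L)
  sim <- simulate_experiment(cfg, step_profile(0.5), 9)
  proc <- process_events(sim$events, induction_start_h = 3)
  s <- proc$summaries
  # strain fraction at t = 0 recovered within 2 points of the true 10:1 mix
  true_f <- sim$reactor$fraction_interest[1L]
  expect_lt(abs(s$fraction_interest[1L] - true_f), 0.02)
  # fraction trajectory tracks the simulator truth
  merged <- merge(s[, c("time_h", "fraction_interest")], sim$reactor,
                  by = "time_h")
  expect_lt(max(abs(merged$fraction_interest.x - merged$fraction_interest.y)),
            0.03)
  # median iPOI at late times recovers the simulated non-burnout content
  last <- sim$snapshots[[length(sim$times)]]
  li <- last[last$strain == "interest", ]
  true_med <- weighted_median <- median(li$trf[!li$burnout])
  got <- s$median_iPOI_rpu[nrow(s)]
  expect_lt(abs(got - true_med) / true_med, 3 * cfg$noise_cv + 0.1)
  # baseline subtraction: pre-induction summaries sit at ~0
  expect_lt(max(abs(s$median_iPOI_rpu[s$time_h < 3])), 0.02)
})

test_that("sample summaries satisfy their count and statistic invariants", {
  int <- data.frame(time_h = 5, GRN_B = c(1, 2, 10), BLU_V = 0, ORG_G = c(1, 1, 7))
  acc <- data.frame(time_h = 5, GRN_B = 0, BLU_V = 0.2, ORG_G = 0.5)
  s <- summarize_sample(int, acc, n_unclassified = 2L)
  expect_equal(s$n_after_gate, 6L)
  expect_equal(s$fraction_interest, 3 / 4)
  expect_equal(s$median_iPOI_rpu, 2)
  expect_gt(s$mean_upr_rpu, s$median_upr_rpu)  # right-skewed: mean > median
  one <- summarize_sample(int[1, ], acc[0, ], 0L)
  expect_equal(one$median_iPOI_rpu, one$mean_upr_rpu * 1)  # single event: both = value
  expect_warning(summarize_sample(int[0, ], acc, 0L), "missing")
})

test_that("induction level normalizes against the campaign maximum", {
  expect_equal(induction_level(rep(2, 100), 2), 1)
  expect_equal(induction_level(rep(0.5, 100), 2), 0.25)
  expect_equal(induction_level(rnorm(100, 0, 1e-6), 2), 0, tolerance = 1e-5)
  expect_warning(v <- induction_level(numeric(0), 2), "no accessory")
  expect_true(is.na(v))
  expect_error(induction_level(1, -1), "positive")
})

test_that("measured induction scales linearly with duty in the simulator", {
  get_ind <- function(duty) {
    cfg <- small_cfg(events_per_sample = 3000L)
    sim <- simulate_experiment(cfg, step_profile(duty), 9)
    proc <- process_events(sim$events, induction_start_h = 3)
    acc <- proc$accessory
    mean(acc$ORG_G[acc$time_h >= 7.5])
  }
  full <- get_ind(1)
  half <- get_ind(0.5)
  expect_equal(half / full, 0.5, tolerance = 0.1)
})
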