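test_that("identical config and seed give bit-identical runs and event tables", {
  cfg <- small_cfg()
  s1 <- simulate_population(cfg, step_profile(0.6), 6)
  s2 <- simulate_population(cfg, step_profile(0.6), 6)
  expect_identical(s1$reactor, s2$reactor)
  expect_identical(s1$snapshots[[5]], s2$snapshots[[5]])
  e1 <- emulate_cytometry(s1$snapshots[[5]], cfg, seed = 99)
  e2 <- emulate_cytometry(s2$snapshots[[5]], cfg, seed = 99)
  expect_identical(e1, e2)
})

test_that("uninduced cultures show no burnout, full growth and no secretion", {
  cfg <- small_cfg()
  sim <- simulate_population(cfg, constant_induction(0, from = 0), 10)
  r <- sim$reactor
  expect_true(all(r$frac_burnout == 0))
  expect_true(all(abs(r$dilution_rate - cfg$mu0) < 1e-6))
  expect_true(all(r$media_sec < 1e-9))
})

test_that("turbidostat keeps total population weight conserved and fractions sane", {
  cfg <- small_cfg()
  sim <- simulate_population(cfg, step_profile(1), 12)
  for (s in sim$snapshots) expect_equal(sum(s$weight), 1, tolerance = 1e-9)
  f0 <- sim$reactor$fraction_interest[1L]
  expect_equal(f0, 1 - cfg$accessory_ratio, tolerance = 0.01)
  # induced interest cells grow slower than the accessory strain
  expect_lt(sim$reactor$fraction_interest[nrow(sim$reactor)], f0)
})

test_that("full induction produces a transient accumulator wave peaking at 2-4 h", {
  cfg <- scenario_config("scfv", n_cells = 2000L, seed = 4)
  sim <- simulate_population(cfg, step_profile(1), 27)
  last <- sim$snapshots[[length(sim$snapshots)]]
  li <- last[last$strain == "interest", ]
  thr <- 10^(mean(log10(li$trf)) + 3 * sd(log10(li$trf)))
  frac <- vapply(sim$snapshots, function(s) {
    si <- s[s$strain == "interest", ]
    sum(si$weight[si$trf > thr]) / sum(si$weight)
  }, numeric(1L))
  pk <- which.max(frac)
  t_peak <- sim$times[pk] - 3
  expect_gte(t_peak, 2)
  expect_lte(t_peak, 4)
  expect_gt(max(frac), 0.2)          # a substantial subpopulation
  expect_lt(frac[length(frac)], 0.01) # transient: gone by 24 h
  # accumulators carry an order of magnitude more internal protein
  sp <- sim$snapshots[[pk]]; spi <- sp[sp$strain == "interest", ]
  hi <- spi$trf > thr
  expect_gte(median(spi$trf[hi]) / median(spi$trf[!hi]), 10)
})

test_that("growth-rate depression accompanies the accumulator wave", {
  cfg <- scenario_config("scfv", n_cells = 2000L, seed = 4)
  sim <- simulate_population(cfg, step_profile(1), 15)
  dip <- 1 - min(sim$reactor$dilution_rate) / cfg$mu0
  expect_gte(dip, 0.3)
})

test_that("the adaptation-deficient scenario burns out and never recovers", {
  cfg <- small_cfg("hac1ko", n_cells = 1000L)
  sim <- simulate_population(cfg, step_profile(1), 27)
  r <- sim$reactor
  expect_gt(max(r$frac_burnout), 0.9)
  # the strain of interest is progressively diluted away
  expect_lt(r$fraction_interest[nrow(r)], 0.3 * r$fraction_interest[1L])
})

test_that("secretion dose-response is non-monotonic for scFv and plateaus for amylase", {
  duties <- c(0.3, 0.5, 1)
  sec_at <- function(scn) vapply(duties, function(d) {
    cfg <- scenario_config(scn, n_cells = 1000L, dt = 0.04, seed = 7)
    sim <- simulate_population(cfg, step_profile(d), 27)
    sim$reactor$media_sec[nrow(sim$reactor)]
  }, numeric(1L))
  scfv <- sec_at("scfv")
  expect_gt(max(scfv[1:2]), 1.15 * scfv[3])   # interior optimum
  amylase <- sec_at("amylase")
  expect_gt(amylase[2], amylase[1])           # still rising at mid induction
  expect_gt(amylase[3], 0.85 * amylase[2])    # but saturating, not collapsing
})

test_that("cytometry emulation respects gate structure, strain markers and debris rate", {
  cfg <- small_cfg(events_per_sample = 5000L)
  sim <- simulate_population(cfg, step_profile(0.5), 6)
  ev <- emulate_cytometry(sim$snapshots[[8]], cfg, time_h = 5.25, seed = 21)
  expect_equal(nrow(ev), 5000L)
  # ~5% debris/doublets outside the FSC gate
  out_frac <- mean(ev$FSC < 1000 | ev$FSC > 2000)
  expect_gt(out_frac, 0.03); expect_lt(out_frac, 0.08)
  # strain demultiplexing in the RPU domain separates the marker cleanly
  refs <- default_rpu_references()
  blu <- ev$BLU_V / ev$FSC / refs[["BLU_V"]]
  expect_gt(mean(blu > 6e-2), 0.05)   # accessory cells present
  expect_gt(mean(blu < 3e-2), 0.80)   # interest cells dominate
  expect_lt(mean(blu >= 3e-2 & blu <= 6e-2), 0.02)  # thin dead band
  expect_error(emulate_cytometry(sim$snapshots[[1]][0, ], cfg), "empty")
})

test_that("zero-content cells yield pure autofluorescence in fluorescence channels", {
  cfg <- small_cfg()
  snap <- data.frame(strain = "interest", expr = 1, trf = 0, upr = 0, red = 0,
                     capacity = 1, burnout = FALSE, weight = 1)
  ev <- emulate_cytometry(snap, cfg, seed = 3)
  refs <- default_rpu_references()
  grn <- ev$GRN_B / ev$FSC / refs[["GRN_B"]]
  # autofluorescence-only: well below any biological signal level
  expect_lt(median(grn), 0.02)
})

test_that("bead assay is linear in concentration with a stable blank", {
  cfg <- small_cfg()
  med_at <- function(conc, seed) {
    ev <- gate_beads(emulate_bead_assay(conc, cfg, seed = seed))
    median(ev$GRN_B)
  }
  blank <- med_at(0, 31)
  m1 <- med_at(2, 32) - blank
  m2 <- med_at(4, 33) - blank
  expect_equal(m2 / m1, 2, tolerance = 0.05)
  expect_equal(med_at(0, 34), blank, tolerance = 0.05 * blank)
  expect_error(emulate_bead_assay(-1, cfg), "non-negative")
})

test_that("configuration validation rejects unstable or nonsensical settings", {
  expect_error(sim_config(dt = 0.2), "0.05")
  expect_error(sim_config(accessory_ratio = 1.2), "\\[0, 1\\)")
  expect_error(sim_config(mu0 = -0.1), "positive")
  expect_error(sim_config(clog = -1), "non-negative")
  expect_error(simulate_population(small_cfg(), step_profile(1), 0.2),
               "sampling interval")
})

test_that("reporter series generator matches its configured physiology", {
  rs <- reporter_series(noise_cv = 0, seed = 1)
  expect_equal(rs$truth$Kdil, 60 * log(2) / 90)
  expect_equal(rs$truth$Kprd, 60 * log(2) / 20)
  # noise-free series equals the deterministic trajectory
  traj <- simulate_ode(rs$truth, constant_induction(1, from = 0),
                       rs$series$time_h)
  expect_equal(rs$series$value, traj$Trf, tolerance = 1e-10)
  # seeded noise is reproducible
  a <- reporter_series(seed = 5); b <- reporter_series(seed = 5)
  expect_identical(a$series, b$series)
})
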