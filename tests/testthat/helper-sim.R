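# small, fast simulator configurations shared across test files
small_cfg <- function(scenario = "scfv", ...) {
  args <- utils::modifyList(
    list(scenario = scenario, n_cells = 500L, events_per_sample = 2000L,
         dt = 0.04, seed = 11L),
    list(...))
  do.call(scenario_config, args)
}

# induction at `duty` after a dark baseline
step_profile <- function(duty, dark_h = 3) {
  induction_profile(c(0, dark_h), c(0, duty))
}
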