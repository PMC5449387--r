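# Shared fixtures. Heavy simulate/fit results are memoized so several test
# files (and the acceptance tests) can reuse them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

water20 <- solvent_conditions(20)

# Small, fast SV setting for unit tests: short cell sweep, coarse radial grid.
tiny_protocol <- function(rpm = 50000, n_scans = 12, dt = 450) {
  rotor_protocol(rpm, 20, scan_times = seq_len(n_scans) * dt)
}

tiny_geometry <- cell_geometry()

# One-species scan set (hexamer-like), coarse grid.
tiny_single_scans <- function(noise = 0, seed = 5) {
  comp <- mixture_components(loading = 1, mass = 27084, vbar = 0.73,
                             f_ratio = 1.27)
  simulate_mixture(comp, tiny_geometry, tiny_protocol(), noise_sigma = noise,
                   seed = seed, n_radial = 200)
}

# Full built-in scenario reports (expensive; shared across files).
scenario_report <- function(name, seed = 1L) {
  memo(paste0("report_", name, "_", seed), {
    run_scenario(builtin_scenarios(seed)[[name]])
  })
}
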