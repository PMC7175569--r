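# Small grids and populations built in code for the unit tests.

# uniform grid of one habitat class, patch labels all connectivity
uniform_grid <- function(nrow, ncol, class = HABITAT[["DISPERSAL"]]) {
  habitat_grid(matrix(class, nrow, ncol),
               matrix(PATCH[["CONNECTIVITY"]], nrow, ncol))
}

# a single 20x20 breeding patch labelled SOURCE, used for settlement tests
breeding_patch_grid <- function(nrow = 20, ncol = 20) {
  habitat_grid(matrix(HABITAT[["BREEDING"]], nrow, ncol),
               matrix(PATCH[["SOURCE"]], nrow, ncol))
}

# fresh state on a grid without running any dispersal
new_test_state <- function(grid, n = 10, demography = demography_params(),
                           genetics = genetics_params(), seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(initialize_founders(n, grid, genetics, demography))
}

# deterministic CS3 run helper
run_cs3 <- function(n_founders, ms = "shy", years = 200, seed = 1,
                    replicate = 1, demography = demography_params()) {
  cfg <- sim_config(landscape_spec(control = "CS3"), ms = ms,
                    n_founders = n_founders, years = years,
                    master_seed = seed, demography = demography)
  run_simulation(cfg, replicate)
}
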