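# Shared fixtures for the test suite. Everything is built in code; the
# reduced problem sizes (few files, short leaves) keep the suite fast while
# exercising the same code paths as full-scale runs.

default_params <- mech_params()

# Reference schedule used by most tissue tests: the full-scale wheat
# configuration with internal lengths fixed at the known inverse-problem
# solution (recomputed exactly in test-fitting / test-acceptance).
test_schedule <- function(a1 = 0.69, a2 = 5.04)
  growth_schedule(a1 = a1, a2 = a2, li0 = 14.74, li_max = 40.315,
                  t_elong = 71.09)

# A small zonation: short leaf so runs finish in well under a second.
small_zonation <- function(stop_length = 0.8)
  zonation_config(L_DZ = 0.15, L_GZ = 0.6, stop_length = stop_length,
                  max_time = 500)

# Homogeneous tissue: n identical files of identical isotonic cells; no
# zonation effects within the horizon (zones pushed far out).
homogeneous_tissue <- function(n_files = 3, n_cells = 3, li = 20,
                               schedule = test_schedule()) {
  lengths <- rep(list(rep(li, n_cells)), n_files)
  leaf_tissue_from_lengths(
    lengths, default_params, schedule,
    zonation = zonation_config(L_DZ = 1e5, L_GZ = 2e5, stop_length = 3e5),
    li = rep(list(rep(li, n_cells)), n_files))
}

# memoised expensive fixtures -------------------------------------------
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# The inverse-problem solution for the packaged constants (~2 s).
wheat_inverse <- function()
  fixture("inverse", function() solve_inverse_problem())

# A scaled-down full run (20 files, full zonation) shared by the
# acceptance criteria on profiles, bookkeeping and analytics (~3 s).
scaled_full_sim <- function()
  fixture("full20", function()
    run_simulation(n_files = 20,
                   schedule = wheat_schedule(inverse = wheat_inverse()),
                   seed = 101, record = "pressures"))
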