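# Shared fixtures for the test suite. All fixtures are generated in code;
# nothing is read from disk except the shipped polymer constants file.

# Parameter sets silenced for out-of-range warnings (tests often switch
# individual terms off, which model_params() flags for interactive users).
quiet_params <- function(...) suppressWarnings(model_params(...))

# Small deterministic search grids so minimization tests stay fast; accuracy
# at these sizes is itself covered by the refinement-convergence test.
small_grid <- function(...) {
  grid_spec(n = 8, n_single = 32, n_refine = 5, refine = 2,
            footprint_n = 96, ...)
}

coarse_grid <- function(...) {
  grid_spec(n = 6, n_single = 24, n_refine = 4, refine = 2,
            footprint_n = 64, ...)
}

# Mid-range parameter sets for the two regimes of the stability analyses.
params_no_spreading <- function(c0 = 0.02) {
  quiet_params(kb = 100, c0 = c0, dp = 6, lambda = 0)
}
params_spreading <- function(lambda = 4, c0 = 0) {
  quiet_params(kb = 100, c0 = c0, dp = 6, lambda = lambda)
}

expect_rel_equal <- function(object, expected, rtol) {
  expect_lt(abs(object - expected), rtol * max(abs(expected), .Machine$double.eps))
}
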