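# Shared fixtures: schemes, tissue definitions and source specs used across
# the test files. Everything is generated in code; seeds are fixed locally
# in the tests that draw random numbers.

two_te_scheme <- function(te = c(60, 150)) sim_scheme(te)

ie_csf_specs <- function() scenario_spec("IE_CSF")$source_specs

ie_csf_params <- function(f_ie = 0.5, t2_ie = 80, s0 = 1)
  tissue_params(s0, c(f_ie, 1 - f_ie), c(t2_ie, 2000))

fixed_csf_config <- function(ie_upper = 300)
  solver_config(list(
    compartment("IE", t2_bounds = c(0, ie_upper)),
    compartment("CSF", t2_fixed = 2000, fixed_source_adc = 3e-3)))

# exhaustive grid-search oracle for a two-compartment voxel with a known
# source matrix: minimizes ||X - s0 * A(t2_ie, f_ie) S|| over a parameter
# grid, independent of the solver's path
grid_oracle_ie <- function(X, S, scheme, s0 = 1,
                           t2_grid = seq(50, 120, by = 0.5),
                           f_grid = seq(0.3, 0.7, by = 0.005)) {
  best <- c(NA, NA); best_val <- Inf
  for (t2 in t2_grid) for (f in f_grid) {
    A <- build_mixing_matrix(scheme,
                             tissue_params(s0, c(f, 1 - f), c(t2, 2000)))
    v <- sum((X - A %*% S)^2)
    if (v < best_val) { best_val <- v; best <- c(t2, f) }
  }
  list(t2_ie = best[1], f_ie = best[2], value = best_val)
}
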