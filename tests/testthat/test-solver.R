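test_that("mixing initialization sits at the central T2 of each constraint", {
  sch <- acq_scheme(c(60, 150), bvals = 0)
  cfg <- solver_config(list(
    compartment("IE", t2_bounds = c(0, 200)),
    compartment("CSF", t2_fixed = 2000)))
  A <- initialize_mixing(sch, cfg)
  expect_equal(unname(A[, 1]), c(exp(-60 / 100), exp(-150 / 100)),
               tolerance = 1e-12)
  expect_equal(unname(A[, 1]), c(0.5488, 0.2231), tolerance = 1e-4)
  expect_equal(unname(A[, 2]), c(0.9704, 0.9277), tolerance = 1e-4)
  # single TE, fixed T2
  sch1 <- acq_scheme(60, bvals = 0)
  A1 <- initialize_mixing(sch1, solver_config(compartment("x", t2_fixed = 80)))
  expect_equal(A1[1, 1], exp(-60 / 80), tolerance = 1e-12)
})

test_that("T2 projection keeps feasible columns and resets infeasible ones", {
  sch <- acq_scheme(c(60, 150), bvals = 0)
  cfg <- solver_config(list(compartment("IE", t2_bounds = c(0, 200))))
  inside <- matrix(exp(-c(60, 150) / 150), ncol = 1)   # implies T2 = 150
  expect_equal(project_t2_constraints(inside, sch, cfg), inside,
               tolerance = 1e-12)
  outside <- matrix(exp(-c(60, 150) / 400), ncol = 1)  # implies T2 = 400
  proj <- project_t2_constraints(outside, sch, cfg)
  expect_equal(t2_from_column(proj[, 1], sch$echo_times), 100,
               tolerance = 1e-9)                        # midpoint of (0, 200]
  expect_equal(proj[1, 1], outside[1, 1], tolerance = 1e-12)  # scale kept
  # increasing column implies a negative T2: reset
  increasing <- matrix(c(0.5, 0.8), ncol = 1)
  proj2 <- project_t2_constraints(increasing, sch, cfg)
  expect_equal(t2_from_column(proj2[, 1], sch$echo_times), 100,
               tolerance = 1e-9)
  # fixed-T2 compartments always reset to their exact exponential direction
  cfgf <- solver_config(compartment("CSF", t2_fixed = 2000))
  perturbed <- matrix(c(0.97, 0.8), ncol = 1)
  projf <- project_t2_constraints(perturbed, sch, cfgf)
  expect_equal(t2_from_column(projf[, 1], sch$echo_times), 2000,
               tolerance = 1e-6)
})

test_that("factorization is deterministic and validates its inputs", {
  sch <- two_te_scheme(c(60, 100))
  cfg <- fixed_csf_config()
  tp <- ie_csf_params()
  set.seed(5)
  X <- add_rician_noise(mix_signal(tp, synthesize_sources(sch, ie_csf_specs()), sch),
                        sch, 50)
  f1 <- cals_factorize(X, sch, cfg)
  f2 <- cals_factorize(X, sch, cfg)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$S, f2$S)
  expect_error(cals_factorize(matrix(0, 2, 31), sch, cfg), "all-zero")
  expect_error(cals_factorize(-X, sch, cfg), "nonnegative")
  cfg3 <- solver_config(list(compartment("a", c(0, 100)),
                             compartment("b", c(100, 200)),
                             compartment("c", t2_fixed = 2000)))
  expect_error(cals_factorize(X, sch, cfg3), "M > N")
})

test_that("returned factors satisfy the model constraints", {
  sch <- two_te_scheme(c(60, 120))
  cfg <- fixed_csf_config()
  tp <- ie_csf_params()
  set.seed(21)
  for (snr in c(Inf, 50)) {
    X <- add_rician_noise(mix_signal(tp, synthesize_sources(sch, ie_csf_specs()), sch),
                          sch, snr)
    fac <- cals_factorize(X, sch, cfg)
    expect_true(all(fac$A >= 0))
    expect_true(all(fac$S >= 0))
    # fixed-source row pinned exactly
    expect_equal(unname(fac$S[2, ]), exp(-sch$bvals * 3e-3), tolerance = 1e-15)
    # source rows b0-normalized
    expect_equal(unname(rowMeans(fac$S[, sch$b0_idx, drop = FALSE])), c(1, 1),
                 tolerance = 1e-9)
    # every column implies an in-bounds T2
    t2s <- apply(fac$A, 2, function(cl) t2_from_column(pmax(cl, 1e-300),
                                                       sch$echo_times))
    expect_gt(t2s[1], 0); expect_lte(t2s[1], 300)
    expect_equal(t2s[2], 2000, tolerance = 1e-6)
  }
})

test_that("noiseless two-compartment factorization matches a grid-search oracle", {
  sch <- two_te_scheme(c(60, 150))   # large dTE: well-conditioned A
  cfg <- fixed_csf_config()
  tp <- ie_csf_params(f_ie = 0.5, t2_ie = 80)
  # known sources: deterministic isotropic, so the oracle shares them exactly
  S <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0),
                                    gaussian_source_spec(3e-3, 0)))
  X <- mix_signal(tp, S, sch)
  expect_lt(kappa(build_mixing_matrix(sch, tp), exact = TRUE), 10)
  res <- bss_voxel(X, sch, cfg)
  orc <- grid_oracle_ie(X, S, sch)
  expect_equal(res$t2[1], orc$t2_ie, tolerance = 0.5 / orc$t2_ie)
  expect_equal(res$f[1], orc$f_ie, tolerance = 0.005 / orc$f_ie)
  expect_equal(orc$t2_ie, 80, tolerance = 0.01)
  expect_equal(orc$f_ie, 0.5, tolerance = 0.01)
})

test_that("scaling the voxel leaves T2 unchanged and scales s0", {
  sch <- two_te_scheme(c(60, 120))
  cfg <- fixed_csf_config()
  tp <- ie_csf_params()
  set.seed(9)
  X <- mix_signal(tp, synthesize_sources(sch, ie_csf_specs()), sch)
  r1 <- bss_voxel(X, sch, cfg)
  r2 <- bss_voxel(7.5 * X, sch, cfg)
  expect_equal(r2$t2, r1$t2, tolerance = 1e-6)
  expect_equal(r2$f, r1$f, tolerance = 1e-6)
  expect_equal(r2$s0, 7.5 * r1$s0, tolerance = 1e-6)
  expect_equal(r2$epsilon, r1$epsilon, tolerance = 1e-6)
})

test_that("exact factorizations are recognized as a fixed point", {
  sch <- two_te_scheme(c(60, 150))
  cfg <- fixed_csf_config()
  tp <- ie_csf_params()
  S <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0),
                                    gaussian_source_spec(3e-3, 0)))
  X <- mix_signal(tp, S, sch)
  fac <- cals_factorize(X, sch, cfg)
  expect_true(fac$converged)
  expect_lt(min(fac$objective_trace), 1e-6 * sqrt(sum(X^2)))
})

test_that("three-compartment noiseless voxel recovers fractions and T2s", {
  sch <- sim_scheme(c(10, 46, 150))
  cfg <- solver_config(constraint_arm("MYELIN_IE_CSF", "separated_prior"))
  tp <- tissue_params(1, c(0.2, 0.5, 0.3), c(15, 100, 2000))
  set.seed(3)
  X <- mix_signal(tp, synthesize_sources(sch, scenario_spec("MYELIN_IE_CSF")$source_specs),
                  sch)
  res <- bss_voxel(X, sch, cfg)
  expect_equal(res$f, c(0.2, 0.5, 0.3), tolerance = 0.05)
  expect_equal(res$t2[2], 100, tolerance = 0.05)
  expect_equal(res$t2[1], 15, tolerance = 0.15)
  expect_equal(res$t2[3], 2000)
})
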