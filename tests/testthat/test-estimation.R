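test_that("T2 read-out from a column inverts the exponential slope", {
  expect_equal(t2_from_column(c(1, exp(-1)), c(60, 150)), 90, tolerance = 1e-12)
  expect_equal(t2_from_column(c(0.9704, 0.9277), c(60, 150)), 2000,
               tolerance = 1e-3)
  # scale invariance
  expect_equal(t2_from_column(5 * c(1, exp(-1)), c(60, 150)), 90,
               tolerance = 1e-12)
  # flat column -> +Inf sentinel
  expect_identical(t2_from_column(c(0.5, 0.5), c(60, 150)), Inf)
  expect_error(t2_from_column(c(1, 0), c(60, 150)), "positive")
  expect_error(t2_from_column(1, 60), "length")
})

test_that("fraction estimation inverts the exponential b0 system", {
  # single exponential
  r <- estimate_fractions(exp(-60 / 80), 60, 80)
  expect_equal(r$s0, 1, tolerance = 1e-9)
  expect_equal(r$f, 1, tolerance = 1e-12)
  # 2x2 system forward-evaluated at known parameters, then inverted
  te <- c(60, 150); t2 <- c(80, 2000)
  b0 <- 0.5 * exp(-te / 80) + 0.5 * exp(-te / 2000)
  expect_equal(b0, c(0.7214, 0.5406), tolerance = 1e-4)
  r2 <- estimate_fractions(b0, te, t2)
  expect_equal(r2$s0, 1, tolerance = 1e-9)
  expect_equal(r2$f, c(0.5, 0.5), tolerance = 1e-9)
  # homogeneity: doubling the signal doubles s0, leaves f
  r3 <- estimate_fractions(2 * b0, te, t2)
  expect_equal(r3$s0, 2, tolerance = 1e-9)
  expect_equal(r3$f, r2$f, tolerance = 1e-9)
  expect_error(estimate_fractions(b0, te, c(80, 200, 2000)), "undetermined")
  expect_error(estimate_fractions(b0, te, c(80, 80)), "distinct")
})

test_that("T2 read-out and fraction solve round trip to machine precision", {
  sch <- acq_scheme(c(40, 90, 150), bvals = 0)
  cases <- list(
    tissue_params(1.3, c(0.25, 0.75), c(70, 1800)),
    tissue_params(0.8, c(0.6, 0.3, 0.1), c(15, 90, 2000)),
    tissue_params(2.0, 1, 110))
  for (tp in cases) {
    A <- build_mixing_matrix(sch, tp, include_s0 = FALSE, include_f = FALSE)
    t2_hat <- apply(A, 2, t2_from_column, echo_times = sch$echo_times)
    expect_equal(t2_hat, tp$t2, tolerance = 1e-9)
    b0 <- as.vector(build_mixing_matrix(sch, tp) %*% rep(1, length(tp$f)))
    fr <- estimate_fractions(b0, sch$echo_times, t2_hat)
    expect_equal(fr$s0, tp$s0, tolerance = 1e-7)
    expect_equal(fr$f, tp$f, tolerance = 1e-7)
  }
})

test_that("source recovery inverts the mixing and respects priors", {
  sch <- two_te_scheme(c(60, 150))
  tp <- ie_csf_params()
  S_true <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0),
                                         gaussian_source_spec(3e-3, 0)))
  A_real <- build_mixing_matrix(sch, tp, include_s0 = FALSE)
  X <- tp$s0 * A_real %*% S_true
  S_rec <- recover_sources(A_real, tp$s0, X)
  expect_equal(S_rec, S_true, tolerance = 1e-9, ignore_attr = TRUE)
  expect_false(attr(S_rec, "ill_conditioned"))
  # singular mixing (equal T2s) fails
  A_bad <- cbind(A_real[, 1], A_real[, 1])
  expect_error(recover_sources(A_bad, 1, X), "singular|distinct")
  # fixed rows re-imposed when a config is provided
  cfg <- fixed_csf_config()
  S_rec2 <- recover_sources(A_real, tp$s0, X + 0.01, config = cfg, scheme = sch)
  expect_equal(unname(S_rec2[2, ]), exp(-sch$bvals * 3e-3), tolerance = 1e-15)
})

test_that("relative factorization error behaves like a relative norm", {
  sch <- two_te_scheme(c(60, 150))
  tp <- ie_csf_params()
  S <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0),
                                    gaussian_source_spec(3e-3, 0)))
  A_real <- build_mixing_matrix(sch, tp, include_s0 = FALSE)
  X <- tp$s0 * A_real %*% S
  expect_equal(factorization_error(X, tp$s0, A_real, S), 0, tolerance = 1e-14)
  # reconstruction = 0.9 X -> epsilon = 0.1
  expect_equal(factorization_error(X, 0.9 * tp$s0, A_real, S), 0.1,
               tolerance = 1e-12)
  # constructed perturbation of known relative size
  set.seed(4)
  P <- matrix(rnorm(length(X)), nrow(X))
  P <- P / sqrt(sum(P^2)) * 0.05 * sqrt(sum(X^2))
  Xp <- X + P
  eps <- factorization_error(Xp, tp$s0, A_real, S)
  expect_equal(eps, 0.05 * sqrt(sum(X^2)) / sqrt(sum(Xp^2)), tolerance = 1e-10)
  # scale invariance
  expect_equal(factorization_error(3 * X, 3 * tp$s0, A_real, S), 0,
               tolerance = 1e-14)
  expect_error(factorization_error(0 * X, 1, A_real, S), "degenerate")
})

test_that("compartment counting follows the threshold rule", {
  expect_identical(count_compartments(c(0.97, 0.03)), 1L)
  expect_identical(count_compartments(c(0.5, 0.5)), 2L)
  expect_identical(count_compartments(c(1, 0)), 1L)
  expect_identical(count_compartments(c(0.9, 0.06, 0.04), threshold = 0.05), 2L)
})

test_that("full voxel estimation recovers a noiseless in-vivo-style voxel", {
  sch <- sim_scheme(c(75.1, 135.1))
  cfg <- solver_config(constraint_arm("IE_CSF", "invivo"))
  tp <- ie_csf_params(f_ie = 0.5, t2_ie = 80)
  set.seed(2)
  X <- mix_signal(tp, synthesize_sources(sch, ie_csf_specs()), sch)
  res <- bss_voxel(X, sch, cfg)
  expect_equal(res$f[1], 0.5, tolerance = 0.01 / 0.5)
  expect_equal(res$t2[1], 80, tolerance = 1 / 80)
  expect_lt(res$epsilon, 0.05)
  expect_identical(res$n_compartments, 2L)
  expect_equal(sum(res$f), 1, tolerance = 1e-9)
})

test_that("pure-CSF voxel yields a near-zero IE fraction", {
  sch <- two_te_scheme(c(60, 120))
  cfg <- fixed_csf_config()
  tp <- tissue_params(1, c(0, 1), c(80, 2000))
  set.seed(14)
  errs <- replicate(50, {
    X <- simulate_voxel(sch, tp, ie_csf_specs(), snr = 50)
    bss_voxel(X, sch, cfg)$f[1]
  })
  expect_lt(mean(errs), 0.1)
})

test_that("noiseless epsilon is tiny and falls with dTE on mixed voxels", {
  cfg <- fixed_csf_config()
  tp <- ie_csf_params()
  # exactly representable voxel: epsilon ~ 0
  sch <- two_te_scheme(c(60, 150))
  S <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0),
                                    gaussian_source_spec(3e-3, 0)))
  res <- bss_voxel(mix_signal(tp, S, sch), sch, cfg)
  expect_lt(res$epsilon, 1e-8)
  # mean epsilon decreases from dTE 10 to dTE 60 over noisy batches
  eps_at <- function(te2, n = 200) {
    schx <- two_te_scheme(c(60, te2))
    set.seed(31)
    mean(replicate(n, bss_voxel(simulate_voxel(schx, tp, ie_csf_specs(), 50),
                                schx, cfg)$epsilon))
  }
  expect_gt(eps_at(70), eps_at(120))
})
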