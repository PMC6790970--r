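#' Scenario source and tissue definitions for the Monte-Carlo studies
#'
#' Three simulated-voxel scenarios are built in:
#' \describe{
#'   \item{`IE_CSF`}{intra/extra-axonal water (MD 0.7e-3, sd 0.3e-3 mm^2/s)
#'     mixed with CSF (MD 3e-3, sd 0.1e-3); T2_CSF = 2000 ms.}
#'   \item{`IC_EC`}{intra-cellular (MD 0.6e-3, sd 0.3e-3) vs extra-cellular
#'     (MD 0.8e-3, sd 0.1e-3) water; T2_EC = 100 ms.}
#'   \item{`MYELIN_IE_CSF`}{a fast-decaying myelin-water pool (T2 = 15 ms,
#'     MD 0.3e-3, sd 0.1e-3) plus IE and CSF.}
#' }
#' The swept compartment (whose true T2 runs over the study's T2 grid) is IE
#' for `IE_CSF` and `MYELIN_IE_CSF`, IC for `IC_EC`.
#'
#' @param scenario Scenario name.
#' @return List with `source_specs`, `t2_fixed_truth` (named, NA for the
#'   swept compartment), `sweep_comp` (index of the swept compartment) and
#'   `names`.
#' @export
scenario_spec <- function(scenario = c("IE_CSF", "IC_EC", "MYELIN_IE_CSF")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    IE_CSF = list(
      names = c("IE", "CSF"),
      source_specs = list(gaussian_source_spec(0.7e-3, 0.3e-3),
                          gaussian_source_spec(3e-3, 0.1e-3)),
      t2_truth = c(NA, 2000), sweep_comp = 1L),
    IC_EC = list(
      names = c("IC", "EC"),
      source_specs = list(gaussian_source_spec(0.6e-3, 0.3e-3),
                          gaussian_source_spec(0.8e-3, 0.1e-3)),
      t2_truth = c(NA, 100), sweep_comp = 1L),
    MYELIN_IE_CSF = list(
      names = c("M", "IE", "CSF"),
      source_specs = list(gaussian_source_spec(0.3e-3, 0.1e-3),
                          gaussian_source_spec(0.7e-3, 0.3e-3),
                          gaussian_source_spec(3e-3, 0.1e-3)),
      t2_truth = c(15, NA, 2000), sweep_comp = 2L))
}

#' Constraint arms of the convergence studies
#'
#' Returns the solver compartments for the named constraint configuration.
#' Two-compartment arms (IE/CSF): `overlapped` (bounds 0-1000 / 0-3000 ms),
#' `separated` (0-300 / 300-3000 ms), `fixed_csf` (IE 0-300 ms, T2_CSF
#' pinned at 2000 ms), each with a `_prior` variant adding the isotropic CSF
#' source prior (D = 3e-3 mm^2/s), plus `invivo` (IE 0-200 ms, T2_CSF fixed
#' 2000 ms, CSF prior). The `IC_EC` scenario has the single `overlapped` arm
#' (0-150 / 0-200 ms, no source prior). Three-compartment arms:
#' `overlapped` (0-40 / 0-300 / 0-3000 ms, no prior) and `separated_prior`
#' (0-40 / 41-300 ms, T2_CSF fixed 2000 ms, CSF prior).
#'
#' @param scenario Scenario name as in [scenario_spec()].
#' @param arm Arm name.
#' @return List of [compartment()] objects in scenario order.
#' @export
constraint_arm <- function(scenario, arm) {
  csf_prior <- 3e-3
  if (scenario == "IE_CSF") {
    switch(arm,
      overlapped = list(compartment("IE", c(0, 1000)),
                        compartment("CSF", c(0, 3000))),
      overlapped_prior = list(compartment("IE", c(0, 1000)),
                              compartment("CSF", c(0, 3000),
                                          fixed_source_adc = csf_prior)),
      separated = list(compartment("IE", c(0, 300)),
                       compartment("CSF", c(300, 3000))),
      separated_prior = list(compartment("IE", c(0, 300)),
                             compartment("CSF", c(300, 3000),
                                         fixed_source_adc = csf_prior)),
      fixed_csf = list(compartment("IE", c(0, 300)),
                       compartment("CSF", t2_fixed = 2000)),
      fixed_csf_prior = list(compartment("IE", c(0, 300)),
                             compartment("CSF", t2_fixed = 2000,
                                         fixed_source_adc = csf_prior)),
      invivo = list(compartment("IE", c(0, 200)),
                    compartment("CSF", t2_fixed = 2000,
                                fixed_source_adc = csf_prior)),
      stop("unknown IE_CSF arm: ", arm))
  } else if (scenario == "IC_EC") {
    switch(arm,
      overlapped = list(compartment("IC", c(0, 150)),
                        compartment("EC", c(0, 200))),
      stop("unknown IC_EC arm: ", arm))
  } else if (scenario == "MYELIN_IE_CSF") {
    switch(arm,
      overlapped = list(compartment("M", c(0, 40)),
                        compartment("IE", c(0, 300)),
                        compartment("CSF", c(0, 3000))),
      separated_prior = list(compartment("M", c(0, 40)),
                             compartment("IE", c(41, 300)),
                             compartment("CSF", t2_fixed = 2000,
                                         fixed_source_adc = csf_prior)),
      stop("unknown MYELIN_IE_CSF arm: ", arm))
  } else stop("unknown scenario: ", scenario)
}

#' Configuration of a Monte-Carlo convergence study
#'
#' The study grid crosses the true T2 of the swept compartment with the
#' second echo time; at every grid point `n_reps` voxels are simulated
#' (fresh source draws and Rician noise per repetition) and estimated with
#' the constrained ALS under the chosen arm. Defaults follow the simulated
#' study conditions: two-compartment studies fix TE1 = 60 ms and sweep TE2
#' from 70 to 150 ms in 31 steps; three-compartment studies fix TE1 = 10 ms
#' and TE3 = 150 ms and sweep TE2 from 20 to 140 ms in 31 steps; 1000
#' repetitions per point.
#'
#' @param scenario Scenario name as in [scenario_spec()].
#' @param arm Constraint arm as in [constraint_arm()]; alternatively supply
#'   `compartments` directly.
#' @param snr Signal-to-noise ratio at the b = 0, shortest-TE volume; `Inf`
#'   for noiseless runs.
#' @param n_reps Repetitions per grid point (default 1000).
#' @param f True volume fractions: a scalar (fraction of the swept/first
#'   compartment; CSF gets the remainder) or the full vector.
#' @param t2_grid True T2 values of the swept compartment (ms).
#' @param te2_grid Second echo times (ms).
#' @param te1 First echo time (ms).
#' @param te3 Third echo time (ms) for three-compartment scenarios.
#' @param seed Integer seed; per-grid-cell streams are derived from it.
#' @param compartments Optional list of [compartment()] overriding `arm`.
#' @param max_iter,tol Solver settings (see [solver_config()]).
#' @return Object of class `bss_sim_config`.
#' @export
simulation_config <- function(scenario, arm = NULL, snr = 50, n_reps = 1000,
                              f = 0.5,
                              t2_grid = seq(50, 150, length.out = 30),
                              te2_grid = NULL, te1 = NULL, te3 = NULL,
                              seed = 1, compartments = NULL,
                              max_iter = 500, tol = 1e-8) {
  sc <- scenario_spec(scenario)
  three <- scenario == "MYELIN_IE_CSF"
  if (is.null(te1)) te1 <- if (three) 10 else 60
  if (is.null(te2_grid))
    te2_grid <- if (three) seq(20, 140, length.out = 31) else seq(70, 150, length.out = 31)
  if (three && is.null(te3)) te3 <- 150
  if (is.null(compartments)) {
    if (is.null(arm)) stop("supply an arm or explicit compartments")
    compartments <- constraint_arm(scenario, arm)
  }
  M <- length(sc$names)
  if (length(f) == 1) {
    if (three) stop("three-compartment scenarios need the full fraction vector")
    f <- c(f, 1 - f)
  }
  if (length(f) != M || abs(sum(f) - 1) > 1e-9)
    stop("fractions must match the scenario and sum to 1")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (any(te2_grid <= te1)) stop("te2_grid must exceed te1")
  structure(list(scenario = scenario, arm = arm, sc = sc, snr = snr,
                 n_reps = n_reps, f = f, t2_grid = as.numeric(t2_grid),
                 te2_grid = as.numeric(te2_grid), te1 = te1, te3 = te3,
                 seed = as.integer(seed), compartments = compartments,
                 max_iter = max_iter, tol = tol),
            class = "bss_sim_config")
}

#' Simulate one noisy multi-compartment voxel
#'
#' @param scheme A `bss_scheme`.
#' @param params A `bss_tissue_params`.
#' @param source_specs List of [gaussian_source_spec()] per compartment.
#' @param snr SNR at (b = 0, TE_min); `Inf` for noiseless.
#' @return N x n signal matrix. Uses the current RNG state.
#' @export
simulate_voxel <- function(scheme, params, source_specs, snr = Inf) {
  S <- synthesize_sources(scheme, source_specs)
  X <- mix_signal(params, S, scheme)
  add_rician_noise(X, scheme, snr)
}

# deterministic, parallel-safe per-cell seed below 2^31
.cell_seed <- function(seed, i, j) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147483629L)
}

#' Run a Monte-Carlo convergence study
#'
#' For every (T2, TE2) grid point, simulates `n_reps` voxels, runs the full
#' per-voxel estimation, and accumulates the mean absolute error of each
#' volume fraction and the mean relative error of each T2, together with
#' their standard errors (SEM = sd / sqrt(n)). Solver failures are counted
#' and excluded from the means rather than aborting the study. Fully
#' deterministic given `config$seed`.
#'
#' @param config A `bss_sim_config`.
#' @param verbose Print per-column progress (default `FALSE`).
#' @return Object of class `bss_error_surface`: list with `t2` and `dte`
#'   axes (ms), arrays `mean_f_abs_error`, `sem_f`, `mean_t2_rel_error`,
#'   `sem_t2` of shape (T2 grid) x (dTE grid) x (compartment), matrix
#'   `n_fail`, and the study metadata.
#' @export
run_convergence_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "bss_sim_config"))
  sc <- config$sc
  M <- length(sc$names)
  n_t2 <- length(config$t2_grid); n_te <- length(config$te2_grid)
  dims <- c(n_t2, n_te, M)
  mf <- sf <- mt <- st <- array(NA_real_, dims)
  nf <- matrix(0L, n_t2, n_te)
  scfg <- solver_config(config$compartments, max_iter = config$max_iter,
                        tol = config$tol)
  for (j in seq_len(n_te)) {
    te <- c(config$te1, config$te2_grid[j], config$te3)
    scheme <- sim_scheme(te)
    dg <- .digest_config(scfg, scheme)
    for (i in seq_len(n_t2)) {
      t2_true <- sc$t2_truth
      t2_true[sc$sweep_comp] <- config$t2_grid[i]
      params <- tissue_params(1, config$f, t2_true)
      set.seed(.cell_seed(config$seed, i, j))
      fe <- te_err <- matrix(NA_real_, config$n_reps, M)
      for (r in seq_len(config$n_reps)) {
        X <- simulate_voxel(scheme, params, sc$source_specs, config$snr)
        res <- tryCatch(
          .bss_voxel_core(X, scheme$echo_times, scheme$b0_idx, dg,
                          config$max_iter, config$tol, 0),
          error = function(e) NULL)
        if (is.null(res)) { nf[i, j] <- nf[i, j] + 1L; next }
        fe[r, ] <- abs(res$f - params$f)
        te_err[r, ] <- abs(res$t2 - params$t2) / params$t2
      }
      mf[i, j, ] <- colMeans(fe, na.rm = TRUE)
      mt[i, j, ] <- colMeans(te_err, na.rm = TRUE)
      n_ok <- colSums(!is.na(fe))
      sf[i, j, ] <- apply(fe, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
      st[i, j, ] <- apply(te_err, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
    }
    if (verbose)
      message(sprintf("TE2 = %.2f ms done (%d/%d)", config$te2_grid[j], j, n_te))
  }
  dn <- list(NULL, NULL, sc$names)
  dimnames(mf) <- dimnames(sf) <- dimnames(mt) <- dimnames(st) <- dn
  structure(list(t2 = config$t2_grid, dte = config$te2_grid - config$te1,
                 mean_f_abs_error = mf, sem_f = sf,
                 mean_t2_rel_error = mt, sem_t2 = st,
                 n_fail = nf, n_reps = config$n_reps,
                 scenario = config$scenario, arm = config$arm,
                 snr = config$snr, compartments = sc$names),
            class = "bss_error_surface")
}

#' @export
print.bss_error_surface <- function(x, ...) {
  cat(sprintf("Convergence study: %s%s, SNR = %g, %d reps/point\n",
              x$scenario, if (!is.null(x$arm)) paste0(" [", x$arm, "]") else "",
              x$snr, x$n_reps))
  cat(sprintf("  grid: %d T2 values x %d dTE values (dTE %.3g-%.3g ms)\n",
              length(x$t2), length(x$dte), min(x$dte), max(x$dte)))
  cat(sprintf("  failures: %d\n", sum(x$n_fail)))
  invisible(x)
}

# pull one (T2 x dTE) error matrix out of a surface
.surface_matrix <- function(surface, metric = c("f_abs", "t2_rel"), comp = 1) {
  metric <- match.arg(metric)
  arr <- if (metric == "f_abs") surface$mean_f_abs_error else surface$mean_t2_rel_error
  arr[, , comp, drop = TRUE]
}

#' Locate the convergence contour of an error surface
#'
#' For each T2 row, finds the first dTE grid cell (scanning along increasing
#' dTE) where the mean error falls below `level`; used to report the
#' "minimum dTE" needed for an accurate estimate.
#'
#' @param surface A `bss_error_surface`, or a plain (T2 x dTE) matrix with
#'   attributes ignored (then `t2`/`dte` must be supplied).
#' @param level Error level of the contour (default 0.1).
#' @param metric `"f_abs"` (fraction absolute error) or `"t2_rel"`.
#' @param comp Compartment index (default 1).
#' @param t2,dte Axes when `surface` is a plain matrix.
#' @return Data frame with columns `t2`, `dte` (first crossing per T2 row);
#'   rows that never cross are omitted, so an empty data frame means the
#'   level is never reached.
#' @export
find_convergence_contour <- function(surface, level = 0.1,
                                     metric = c("f_abs", "t2_rel"),
                                     comp = 1, t2 = NULL, dte = NULL) {
  if (level <= 0) stop("level must be positive")
  if (inherits(surface, "bss_error_surface")) {
    mat <- .surface_matrix(surface, match.arg(metric), comp)
    t2 <- surface$t2; dte <- surface$dte
  } else {
    mat <- as.matrix(surface)
    if (is.null(t2)) t2 <- seq_len(nrow(mat))
    if (is.null(dte)) dte <- seq_len(ncol(mat))
  }
  mat <- matrix(mat, length(t2), length(dte))
  hits <- lapply(seq_along(t2), function(i) {
    k <- which(mat[i, ] < level)[1]
    if (is.na(k)) NULL else data.frame(t2 = t2[i], dte = dte[k])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(t2 = numeric(0), dte = numeric(0)) else out
}

#' Jointly optimal echo-time spacing of a three-compartment study
#'
#' Scores each dTE by the number of T2 grid rows where *all* supplied error
#' surfaces are below `level` (the joint convergence area along that
#' column), and returns the dTE maximizing the area; ties break toward the
#' smaller dTE. When no dTE attains a nonzero area — the per-voxel errors
#' never jointly clear the level — the dTE that jointly minimizes the
#' errors is returned instead: the minimizer of the mean of all supplied
#' surfaces over the T2 axis (`fallback = "min_mean"`), or `NA` with
#' `fallback = "none"`. For a three-compartment study the four relevant
#' surfaces are the volume-fraction errors of the myelin and IE pools and
#' their T2 relative errors.
#'
#' @param surfaces A `bss_error_surface` (the four myelin/IE surfaces are
#'   extracted) or a list of (T2 x dTE) matrices on a shared grid.
#' @param level Error level (default 0.1).
#' @param dte dTE axis when matrices are supplied.
#' @param fallback `"min_mean"` (default) or `"none"`.
#' @return dTE in ms, or `NA` when no dTE attains a nonzero joint area and
#'   `fallback = "none"`.
#' @export
optimal_delta_te <- function(surfaces, level = 0.1, dte = NULL,
                             fallback = c("min_mean", "none")) {
  fallback <- match.arg(fallback)
  if (inherits(surfaces, "bss_error_surface")) {
    s <- surfaces
    comps <- seq_len(min(2L, dim(s$mean_f_abs_error)[3]))
    mats <- c(lapply(comps, function(k) .surface_matrix(s, "f_abs", k)),
              lapply(comps, function(k) .surface_matrix(s, "t2_rel", k)))
    dte <- s$dte
  } else {
    mats <- lapply(surfaces, as.matrix)
    if (is.null(dte)) dte <- seq_len(ncol(mats[[1]]))
  }
  mats <- lapply(mats, function(m) matrix(m, ncol = length(dte)))
  ok <- Reduce(`&`, lapply(mats, function(m) m < level))
  ok <- matrix(ok, ncol = length(dte))
  area <- colSums(ok)
  if (max(area) > 0)
    return(dte[which.max(area)])  # which.max: first (smallest dTE) on ties
  if (fallback == "none") return(NA_real_)
  joint <- Reduce(`+`, lapply(mats, colMeans)) / length(mats)
  dte[which.min(joint)]
}

#' Write an error surface as TSV tables
#'
#' One long-format row per (T2, dTE, compartment) cell with the mean errors
#' and SEMs; suitable for plotting or archiving alongside a study config.
#'
#' @param surface A `bss_error_surface`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_error_surface <- function(surface, path) {
  g <- expand.grid(t2 = surface$t2, dte = surface$dte,
                   compartment = surface$compartments,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$mean_f_abs_error <- as.vector(surface$mean_f_abs_error)
  g$sem_f <- as.vector(surface$sem_f)
  g$mean_t2_rel_error <- as.vector(surface$mean_t2_rel_error)
  g$sem_t2 <- as.vector(surface$sem_t2)
  utils::write.table(g, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
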