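#' Assemble a multi-TE diffusion dataset
#'
#' Bundles one 4D volume per echo time with the shared diffusion protocol
#' and an optional brain mask. All volumes must share the spatial grid; the
#' per-TE (b, g) protocol is identical by assumption (registration across
#' TEs is expected to have been done upstream). When no mask is given,
#' voxels whose b = 0 signal at the shortest TE falls below
#' `mask_rel_threshold` of the volume maximum are excluded.
#'
#' @param volumes List of 4D arrays (x, y, z, volume) or paths to NIfTI
#'   files, one per echo time, ordered as `echo_times`.
#' @param echo_times Echo times in ms.
#' @param bvals,bvecs Diffusion protocol (shared across TEs); see
#'   [acq_scheme()].
#' @param mask Optional 3D logical/0-1 array or NIfTI path.
#' @param mask_rel_threshold Background threshold relative to the maximum
#'   b = 0 signal (default 1e-3), used when `mask` is `NULL`.
#' @return Object of class `bss_multite`: list with `volumes` (list of 4D
#'   arrays), `scheme`, `mask`, `dim`.
#' @export
multite_dataset <- function(volumes, echo_times, bvals, bvecs, mask = NULL,
                            mask_rel_threshold = 1e-3) {
  vols <- lapply(volumes, function(v) {
    if (is.character(v)) v <- RNifti::readNifti(v)
    a <- as.array(v)
    if (length(dim(a)) != 4) stop("each TE volume must be 4D")
    a
  })
  d <- dim(vols[[1]])
  for (v in vols) if (!identical(dim(v), d))
    stop("all TE volumes must share grid and volume count")
  scheme <- acq_scheme(echo_times, bvals, bvecs)
  if (length(vols) != scheme$n_te) stop("one volume per echo time required")
  if (d[4] != scheme$n_meas) stop("4th dimension must match the protocol")
  if (is.null(mask)) {
    b0 <- vols[[1]][, , , scheme$b0_idx[1], drop = FALSE]
    dim(b0) <- d[1:3]
    mask <- b0 > mask_rel_threshold * max(b0)
  } else {
    if (is.character(mask)) mask <- RNifti::readNifti(mask)
    mask <- array(as.array(mask) > 0, d[1:3])
  }
  structure(list(volumes = vols, scheme = scheme, mask = mask, dim = d[1:3]),
            class = "bss_multite")
}

#' Read compartment definitions from a YAML config
#'
#' Expected layout: a top-level `compartments` list whose entries carry
#' `name` and either `t2_bounds: [low, high]` or `t2_fixed`, plus optional
#' `fixed_source_adc` (mm^2/s).
#'
#' @param path YAML file path.
#' @return List of [compartment()] objects.
#' @export
read_compartments_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$compartments)) cfg$compartments else cfg
  lapply(entries, function(e)
    compartment(e$name,
                t2_bounds = if (!is.null(e$t2_bounds)) unlist(e$t2_bounds),
                t2_fixed = e$t2_fixed,
                fixed_source_adc = e$fixed_source_adc))
}

#' Voxelwise pairwise-TE blind source separation
#'
#' Applies the full per-voxel estimation to one pair of echo times of a
#' multi-TE dataset (the in-vivo strategy: a fixed short TE paired with an
#' increasing long TE, M = N = 2). Background voxels get `NA` maps;
#' per-voxel failures are counted and set to `NA`.
#'
#' @param data A `bss_multite`.
#' @param short_te_index,long_te_index Indices into the dataset's echo
#'   times; must differ.
#' @param config A `bss_solver_config` (defaults to the in-vivo constraints:
#'   T2_IE bounded 0-200 ms, T2_CSF fixed at 2000 ms with the isotropic
#'   D = 3e-3 mm^2/s source prior).
#' @param count_threshold Fraction threshold for the compartment-count map.
#' @return Object of class `bss_parameter_maps`: list with 3D maps `s0`,
#'   `epsilon`, `n_compartments`, per-compartment 3D maps `f` and `t2`
#'   (lists), per-compartment 4D `sources`, the pair's `scheme`, `mask`, and
#'   `n_fail`.
#' @export
run_bss_pairwise <- function(data, short_te_index, long_te_index,
                             config = NULL, count_threshold = 0.05) {
  stopifnot(inherits(data, "bss_multite"))
  ij <- c(short_te_index, long_te_index)
  if (length(unique(ij)) != 2) stop("TE indices must be two distinct values")
  if (any(ij < 1 | ij > data$scheme$n_te)) stop("TE index out of range")
  if (is.null(config))
    config <- solver_config(constraint_arm("IE_CSF", "invivo"))
  te <- data$scheme$echo_times[ij]
  scheme <- acq_scheme(te, data$scheme$bvals, data$scheme$bvecs)
  dg <- .digest_config(config, scheme)
  M <- dg$M
  if (M > 2) stop("pairwise processing supports at most two compartments")
  d <- data$dim
  na3 <- array(NA_real_, d)
  maps <- list(s0 = na3, epsilon = na3, n_compartments = na3,
               f = rep(list(na3), M), t2 = rep(list(na3), M),
               sources = rep(list(array(NA_real_, c(d, scheme$n_meas))), M))
  vs <- data$volumes[[ij[1]]]; vl <- data$volumes[[ij[2]]]
  idx <- which(data$mask)
  n_fail <- 0L
  coord <- arrayInd(idx, d)
  for (k in seq_along(idx)) {
    x <- coord[k, 1]; y <- coord[k, 2]; z <- coord[k, 3]
    X <- rbind(vs[x, y, z, ], vl[x, y, z, ])
    res <- tryCatch(
      .bss_voxel_core(X, scheme$echo_times, scheme$b0_idx, dg,
                      config$max_iter, config$tol, config$nonneg_floor,
                      count_threshold),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    maps$s0[x, y, z] <- res$s0
    maps$epsilon[x, y, z] <- res$epsilon
    maps$n_compartments[x, y, z] <- res$n_compartments
    for (i in seq_len(M)) {
      maps$f[[i]][x, y, z] <- res$f[i]
      maps$t2[[i]][x, y, z] <- res$t2[i]
      maps$sources[[i]][x, y, z, ] <- res$s0 * res$f[i] * res$S[i, ]
    }
  }
  names(maps$f) <- names(maps$t2) <- names(maps$sources) <-
    vapply(config$compartments, `[[`, "", "name")
  structure(c(maps, list(scheme = scheme, mask = data$mask, n_fail = n_fail)),
            class = "bss_parameter_maps")
}

#' Write parameter maps as NIfTI files
#'
#' Scalar maps are written as 3D float NIfTI volumes, the disentangled
#' per-compartment signals as one 4D volume each.
#'
#' @param maps A `bss_parameter_maps`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default "bss").
#' @return Character vector of written paths, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, prefix = "bss") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(arr, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr), p)
    paths <<- c(paths, p)
  }
  wr(maps$s0, "s0"); wr(maps$epsilon, "epsilon")
  wr(maps$n_compartments, "ncomp")
  for (nm in names(maps$f)) {
    wr(maps$f[[nm]], paste0("f_", nm))
    wr(maps$t2[[nm]], paste0("t2_", nm))
    wr(maps$sources[[nm]], paste0("source_", nm))
  }
  invisible(paths)
}

#' Fit the diffusion tensor to one signal vector
#'
#' Log-linear least-squares DTI fit: `log S = log S0 - b g' D g`, solved for
#' the six tensor elements (and log S0) by ordinary least squares, or
#' optionally weighted by the squared signal. Nonpositive signals are masked
#' out of the regression. Eigenvalues are clipped at zero before computing
#' the scalar invariants.
#'
#' @param signal Numeric vector of n diffusion signals.
#' @param bvals,bvecs Protocol (n b-values; n x 3 or 3 x n directions).
#' @param weighted Use signal-squared weights (default `FALSE`, the
#'   standard linear regression).
#' @return List of class `bss_tensor_fit` with `tensor` (3 x 3, mm^2/s),
#'   `eigenvalues`, `fa`, `md`, `s0`.
#' @export
fit_dti <- function(signal, bvals, bvecs, weighted = FALSE) {
  signal <- as.numeric(signal)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  n <- length(signal)
  stopifnot(length(bvals) == n, nrow(bvecs) == n)
  keep <- signal > 0
  dw <- bvals > 0 & keep
  if (sum(dw) < 6 || !any(bvals == 0 & keep))
    stop("need >= 6 positive diffusion-weighted signals and a b0")
  g <- bvecs
  # design: log S = c0 - b * (q . d), d = (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz)
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  Xd <- cbind(1, -bvals * Q)[keep, , drop = FALSE]
  y <- log(signal[keep])
  beta <- if (weighted) {
    w <- signal[keep]^2
    unname(stats::lm.wfit(Xd, y, w)$coefficients)
  } else {
    unname(stats::lm.fit(Xd, y)$coefficients)
  }
  Dt <- matrix(c(beta[2], beta[5], beta[6],
                 beta[5], beta[3], beta[7],
                 beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(Dt, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  md <- mean(ev)
  fa <- if (sum(ev^2) == 0) 0 else
    sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  structure(list(tensor = Dt, eigenvalues = ev, fa = min(fa, 1), md = md,
                 s0 = exp(beta[1])),
            class = "bss_tensor_fit")
}

#' Match a multi-echo decay to a mono-exponential T2 dictionary
#'
#' Both the decay and the dictionary atoms exp(-TE/T2) are normalized to
#' unit Euclidean norm; the atom at minimum distance wins, with ties broken
#' toward the smaller T2. The grid spans 0-300 ms at 1 ms by default
#' (nonpositive grid values are dropped, since their atoms are degenerate).
#'
#' @param decay Nonnegative signal vector over the echo times.
#' @param echo_times Echo times in ms (length >= 2).
#' @param t2_grid Candidate T2 values in ms (default `seq(0, 300, by = 1)`).
#' @return Matched T2 in ms.
#' @export
dictionary_t2_match <- function(decay, echo_times, t2_grid = seq(0, 300, by = 1)) {
  decay <- as.numeric(decay)
  if (length(decay) != length(echo_times) || length(decay) < 2)
    stop("decay and echo_times must have equal length >= 2")
  if (all(decay == 0)) stop("all-zero decay cannot be matched")
  t2_grid <- sort(t2_grid[t2_grid > 0])
  d <- decay / sqrt(sum(decay^2))
  atoms <- exp(outer(-as.numeric(echo_times), 1 / t2_grid))
  atoms <- sweep(atoms, 2, sqrt(colSums(atoms^2)), `/`)
  dist2 <- colSums((atoms - d)^2)
  t2_grid[which.min(dist2)]   # which.min: first minimum = smaller T2 on ties
}

#' Generate a synthetic multi-TE phantom with ground truth
#'
#' Builds a small 4D-per-TE dataset from per-region tissue definitions via
#' the forward signal model, with per-voxel source draws and Rician noise.
#' This is a synthetic stand-in for an in-vivo acquisition, intended for
#' pipeline testing; the returned ground truth carries the per-voxel
#' fractions and T2 values it was built from.
#'
#' @param regions List of regions, each a list with `name`, integer vectors
#'   `x`, `y`, `z` selecting the region's voxels, `f` (fractions, summing
#'   to 1), `t2` (ms) and `source_specs` (list of [gaussian_source_spec()]).
#'   Regions must not overlap. Voxels not covered remain background (zero
#'   signal, outside the mask).
#' @param dim Length-3 grid size.
#' @param scheme A `bss_scheme`.
#' @param snr SNR at (b = 0, TE_min); `Inf` for noiseless.
#' @param seed Optional integer seed.
#' @param s0 Proton density (shared; default 1).
#' @return List with `data` (a `bss_multite`) and `truth` (list of 3D maps:
#'   per-compartment `f` and `t2`, plus `region` labels).
#' @export
make_synthetic_phantom <- function(regions, dim, scheme, snr = Inf,
                                   seed = NULL, s0 = 1) {
  if (!is.null(seed)) set.seed(seed)
  d <- as.integer(dim)
  stopifnot(length(d) == 3)
  M <- length(regions[[1]]$f)
  assign_map <- array(0L, d)
  vols <- rep(list(array(0, c(d, scheme$n_meas))), scheme$n_te)
  truth <- list(f = rep(list(array(NA_real_, d)), M),
                t2 = rep(list(array(NA_real_, d)), M),
                region = array(NA_character_, d))
  for (ri in seq_along(regions)) {
    rg <- regions[[ri]]
    if (length(rg$f) != M) stop("all regions must define the same compartments")
    sel <- as.matrix(expand.grid(x = rg$x, y = rg$y, z = rg$z))
    lin <- sel[, 1] + d[1] * (sel[, 2] - 1) + d[1] * d[2] * (sel[, 3] - 1)
    if (any(assign_map[lin] != 0L)) stop("overlapping phantom regions")
    assign_map[lin] <- ri
    params <- tissue_params(s0, rg$f, rg$t2)
    for (k in seq_len(nrow(sel))) {
      X <- simulate_voxel(scheme, params, rg$source_specs, snr)
      for (j in seq_len(scheme$n_te))
        vols[[j]][sel[k, 1], sel[k, 2], sel[k, 3], ] <- X[j, ]
    }
    truth$region[lin] <- rg$name
    for (i in seq_len(M)) {
      truth$f[[i]][lin] <- rg$f[i]
      truth$t2[[i]][lin] <- rg$t2[i]
    }
  }
  data <- multite_dataset(vols, scheme$echo_times, scheme$bvals,
                          scheme$bvecs, mask = assign_map > 0L)
  list(data = data, truth = truth)
}
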