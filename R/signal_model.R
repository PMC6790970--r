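#' Compartment definition for the constrained factorization
#'
#' Each tissue water compartment is described by its transverse relaxation
#' constraint (a T2 interval in ms, or a single fixed T2) and, optionally, a
#' known isotropic diffusion source: when the diffusivity `fixed_source_adc`
#' is given, the compartment's source row is pinned to exp(-b * D) instead of
#' being estimated (the standard prior for CSF, D = 3e-3 mm^2/s).
#'
#' @param name Compartment label, e.g. "IE", "CSF", "myelin".
#' @param t2_bounds Length-2 numeric `(low, high)` in ms with
#'   `0 <= low < high`; ignored when `t2_fixed` is given.
#' @param t2_fixed Single fixed T2 value in ms (> 0).
#' @param fixed_source_adc Optional isotropic diffusivity D in mm^2/s (>= 0)
#'   defining a known source signal exp(-b * D).
#' @return An object of class `bss_compartment`.
#' @examples
#' csf <- compartment("CSF", t2_fixed = 2000, fixed_source_adc = 3e-3)
#' ie  <- compartment("IE", t2_bounds = c(0, 300))
#' @export
compartment <- function(name, t2_bounds = NULL, t2_fixed = NULL,
                        fixed_source_adc = NULL) {
  if (is.null(t2_bounds) && is.null(t2_fixed))
    stop("compartment needs t2_bounds or t2_fixed")
  if (!is.null(t2_fixed)) {
    t2_fixed <- as.numeric(t2_fixed)
    if (length(t2_fixed) != 1 || !is.finite(t2_fixed) || t2_fixed <= 0)
      stop("t2_fixed must be a single positive value (ms)")
    t2_bounds <- NULL
  } else {
    t2_bounds <- as.numeric(t2_bounds)
    if (length(t2_bounds) != 2 || any(!is.finite(t2_bounds)) ||
        t2_bounds[1] < 0 || t2_bounds[1] >= t2_bounds[2])
      stop("t2_bounds must satisfy 0 <= low < high")
  }
  if (!is.null(fixed_source_adc)) {
    fixed_source_adc <- as.numeric(fixed_source_adc)
    if (length(fixed_source_adc) != 1 || fixed_source_adc < 0)
      stop("fixed_source_adc must be a nonnegative diffusivity (mm^2/s)")
  }
  structure(list(name = as.character(name), t2_bounds = t2_bounds,
                 t2_fixed = t2_fixed, fixed_source_adc = fixed_source_adc),
            class = "bss_compartment")
}

# central T2 of a compartment's admissible interval (fixed value if pinned)
.t2_center <- function(comp) {
  if (!is.null(comp$t2_fixed)) comp$t2_fixed else mean(comp$t2_bounds)
}

#' Ground-truth tissue parameters of a voxel
#'
#' @param s0 Proton-density scale (signal units, > 0 for physical voxels).
#' @param f Volume fractions, one per compartment; each in \[0, 1\], summing
#'   to 1.
#' @param t2 T2 per compartment in ms, all positive and pairwise distinct
#'   (the factorization's mixing matrix is singular for equal T2s).
#' @return An object of class `bss_tissue_params`.
#' @export
tissue_params <- function(s0, f, t2) {
  f <- as.numeric(f); t2 <- as.numeric(t2); s0 <- as.numeric(s0)
  if (length(s0) != 1 || !is.finite(s0) || s0 < 0) stop("invalid s0")
  if (length(f) != length(t2)) stop("f and t2 must have the same length")
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) stop("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(!is.finite(t2)) || any(t2 <= 0)) stop("t2 values must be positive")
  if (anyDuplicated(t2)) stop("t2 values must be pairwise distinct")
  structure(list(s0 = s0, f = f, t2 = t2), class = "bss_tissue_params")
}

#' Gaussian diffusion source specification
#'
#' A simulated compartmental source draws one apparent diffusivity per
#' gradient direction from N(mean_diffusivity, direction_std^2), truncated at
#' zero, and decays mono-exponentially with b along each direction. A
#' `direction_std` of 0 yields a deterministic isotropic source.
#'
#' @param mean_diffusivity Mean apparent diffusivity in mm^2/s (> 0).
#' @param direction_std Standard deviation of per-direction diffusivities in
#'   mm^2/s (>= 0).
#' @return An object of class `bss_source_spec`.
#' @export
gaussian_source_spec <- function(mean_diffusivity, direction_std = 0) {
  if (mean_diffusivity <= 0) stop("mean_diffusivity must be positive")
  if (direction_std < 0) stop("direction_std must be nonnegative")
  structure(list(mean_diffusivity = mean_diffusivity,
                 direction_std = direction_std),
            class = "bss_source_spec")
}

#' Build the exponential mixing matrix
#'
#' Element (j, i) of the full mixing matrix is
#' `s0 * f_i * exp(-TE_j / T2_i)`: the weight with which compartment i's
#' diffusion source enters the measurement at echo time j. Variants excluding
#' the proton density and/or the volume fractions are used for
#' column-direction comparisons and for the relative factorization error,
#' where the scale is carried separately.
#'
#' @param scheme A `bss_scheme`.
#' @param params A `bss_tissue_params`.
#' @param include_s0,include_f Include the `s0` / `f_i` factors (default
#'   both `TRUE`).
#' @return N x M numeric matrix (rows = echo times, columns = compartments).
#' @examples
#' sch <- acq_scheme(c(60, 150), bvals = 0)
#' tp <- tissue_params(1, c(0.5, 0.5), c(80, 2000))
#' build_mixing_matrix(sch, tp, include_s0 = FALSE, include_f = FALSE)
#' @export
build_mixing_matrix <- function(scheme, params, include_s0 = TRUE,
                                include_f = TRUE) {
  stopifnot(inherits(scheme, "bss_scheme"), inherits(params, "bss_tissue_params"))
  A <- exp(outer(-scheme$echo_times, 1 / params$t2))
  if (include_f) A <- sweep(A, 2, params$f, `*`)
  if (include_s0) A <- A * params$s0
  A
}

#' Synthesize compartmental diffusion sources
#'
#' Generates the M x n source matrix for a list of Gaussian source
#' specifications: per-direction apparent diffusivities are drawn
#' independently for each compartment (truncated at 0), and each source
#' decays as exp(-b * ADC_dir). All b = 0 entries equal 1 exactly, the
#' attenuation-contrast convention that the solver relies on. Draws use the
#' current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param scheme A `bss_scheme` with at least one b = 0 volume.
#' @param specs List of `bss_source_spec`, one per compartment.
#' @return M x n numeric matrix of source signals.
#' @export
synthesize_sources <- function(scheme, specs) {
  stopifnot(inherits(scheme, "bss_scheme"), length(specs) >= 1)
  if (inherits(specs, "bss_source_spec")) specs <- list(specs)
  S <- matrix(0, length(specs), scheme$n_meas)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "bss_source_spec"))
    adc <- stats::rnorm(scheme$n_meas, sp$mean_diffusivity, sp$direction_std)
    adc <- pmax(adc, 0)
    S[i, ] <- exp(-scheme$bvals * adc)
  }
  S[, scheme$b0_idx] <- 1
  S
}

#' Mix compartmental sources into a measured multi-TE signal matrix
#'
#' Forward model: `X = A S`, the TE-weighted sum of the compartmental
#' sources, with `A` the full mixing matrix (including `s0` and `f`).
#'
#' @param params A `bss_tissue_params`.
#' @param sources M x n source matrix (one row per compartment).
#' @param scheme A `bss_scheme`.
#' @return N x n nonnegative signal matrix.
#' @export
mix_signal <- function(params, sources, scheme) {
  sources <- as.matrix(sources)
  if (nrow(sources) != length(params$f))
    stop("compartment count of params must equal rows of sources")
  if (ncol(sources) != scheme$n_meas)
    stop("sources do not match the scheme's measurement count")
  build_mixing_matrix(scheme, params) %*% sources
}

#' Add Rician noise at a stated SNR
#'
#' Magnitude-MRI noise: each entry x becomes sqrt((x + e1)^2 + e2^2) with
#' e1, e2 ~ N(0, sigma^2). The noise level is referenced to the strongest
#' measurement, sigma = X(b = 0, TE_min) / snr (first b = 0 volume at the
#' shortest echo time of the noiseless signal).
#'
#' @param signal N x n noiseless signal matrix.
#' @param scheme The `bss_scheme` the signal was generated under.
#' @param snr Positive scalar signal-to-noise ratio; `Inf` returns the
#'   signal unchanged.
#' @param seed Optional integer seed (draws otherwise use the current RNG
#'   state).
#' @return Noisy nonnegative signal matrix of the same shape.
#' @export
add_rician_noise <- function(signal, scheme, snr, seed = NULL) {
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    stop("snr must be a positive scalar")
  signal <- as.matrix(signal)
  if (is.infinite(snr)) return(signal)
  if (!is.null(seed)) set.seed(seed)
  sigma <- signal[1, scheme$b0_idx[1]] / snr
  e1 <- matrix(stats::rnorm(length(signal), 0, sigma), nrow(signal))
  e2 <- matrix(stats::rnorm(length(signal), 0, sigma), nrow(signal))
  sqrt((signal + e1)^2 + e2^2)
}
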