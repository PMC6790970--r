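#' Define a multi-echo diffusion acquisition scheme
#'
#' The measurement grid for the factorization: `N` echo times, each of which
#' repeats the identical diffusion protocol of `n` volumes described by
#' b-values and gradient directions. Every scheme must contain at least one
#' non-diffusion-weighted (b = 0) volume, since the sources are normalized to
#' unit signal at b = 0.
#'
#' @param echo_times Numeric vector of echo times TE in ms, strictly
#'   increasing, all positive.
#' @param bvals Numeric vector of b-values in s/mm^2, one per diffusion
#'   volume; at least one must be 0.
#' @param bvecs Gradient directions: a 3 x n or n x 3 numeric matrix (FSL
#'   dialect, auto-detected by shape). Directions of b > 0 volumes must have
#'   unit norm; b = 0 rows may be zero. May be `NULL` when all volumes share
#'   b = 0 (pure relaxometry).
#' @return An object of class `bss_scheme` with elements `echo_times`,
#'   `bvals`, `bvecs` (n x 3, possibly all-zero rows for b = 0), `n_meas`,
#'   `n_te` and `b0_idx` (indices of the b = 0 volumes).
#' @examples
#' sch <- acq_scheme(c(60, 150), bvals = c(0, 1000, 1000),
#'                   bvecs = cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' sch$b0_idx
#' @export
acq_scheme <- function(echo_times, bvals, bvecs = NULL) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1 || any(!is.finite(echo_times)) || any(echo_times <= 0))
    stop("echo_times must be positive and finite")
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be strictly increasing")
  bvals <- as.numeric(bvals)
  n <- length(bvals)
  if (n < 1 || any(bvals < 0)) stop("bvals must be nonnegative")
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  if (is.null(bvecs)) {
    if (any(bvals > 0)) stop("bvecs required when b > 0 volumes are present")
    bvecs <- matrix(0, n, 3)
  } else {
    bvecs <- as.matrix(bvecs)
    if (nrow(bvecs) == 3 && ncol(bvecs) == n && n != 3) bvecs <- t(bvecs)
    if (nrow(bvecs) == 3 && ncol(bvecs) == 3 && n == 3) {
      # ambiguous 3x3: assume rows = volumes (n x 3)
    }
    if (nrow(bvecs) != n || ncol(bvecs) != 3)
      stop("bvecs must be 3 x n or n x 3")
    nrm <- sqrt(rowSums(bvecs^2))
    dw <- bvals > 0
    if (any(dw) && any(abs(nrm[dw] - 1) > 1e-4))
      stop("gradient directions of b > 0 volumes must have unit norm")
  }
  structure(list(echo_times = echo_times, bvals = bvals, bvecs = bvecs,
                 n_meas = n, n_te = length(echo_times),
                 b0_idx = which(bvals == 0)),
            class = "bss_scheme")
}

#' @export
print.bss_scheme <- function(x, ...) {
  cat("Multi-TE diffusion acquisition scheme\n")
  cat(sprintf("  %d echo times (ms): %s\n", x$n_te,
              paste(signif(x$echo_times, 5), collapse = ", ")))
  cat(sprintf("  %d diffusion volumes per TE (%d with b = 0), b up to %g s/mm^2\n",
              x$n_meas, length(x$b0_idx), max(x$bvals)))
  invisible(x)
}

#' Deterministic quasi-uniform directions on the half sphere
#'
#' Fibonacci-spiral points, used for simulated protocols where only the count
#' of directions matters (the per-direction diffusivity draws are not tied to
#' orientation).
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n          # upper half sphere
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Simulation default scheme: one b0 plus 30 directions at b = 1000
#'
#' The diffusion protocol used throughout the Monte-Carlo studies: a single
#' non-diffusion-weighted volume followed by 30 gradient directions at
#' b = 1000 s/mm^2, repeated identically at each echo time.
#'
#' @param echo_times Echo times in ms.
#' @param n_dirs Number of diffusion-weighted directions (default 30).
#' @param bvalue b-value of the weighted volumes in s/mm^2 (default 1000).
#' @return A `bss_scheme`.
#' @export
sim_scheme <- function(echo_times, n_dirs = 30, bvalue = 1000) {
  acq_scheme(echo_times,
             bvals = c(0, rep(bvalue, n_dirs)),
             bvecs = rbind(c(0, 0, 0), fibonacci_directions(n_dirs)))
}

#' Read FSL-style bvals/bvecs text files
#'
#' @param bval_file Path to the whitespace-separated b-values file.
#' @param bvec_file Path to the gradients file (3 rows of n, or n rows of 3).
#' @return List with `bvals` (numeric) and `bvecs` (n x 3 matrix).
#' @export
read_bvals_bvecs <- function(bval_file, bvec_file) {
  bvals <- scan(bval_file, quiet = TRUE)
  tab <- as.matrix(utils::read.table(bvec_file))
  dimnames(tab) <- NULL
  if (nrow(tab) == 3 && ncol(tab) != 3) tab <- t(tab)
  if (ncol(tab) != 3 || nrow(tab) != length(bvals))
    stop("bvecs shape does not match bvals length")
  list(bvals = bvals, bvecs = tab)
}
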