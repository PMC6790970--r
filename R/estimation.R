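#' T2 implied by a mixing-matrix column
#'
#' T2 = (TE_l - TE_k) / log(a_k / a_l), evaluated on the leading (shortest
#' TE) pair of entries; later echoes of a fast-decaying compartment sit at
#' the numerical floor and carry no slope information. A flat column
#' (entries equal within 1e-12) returns the `+Inf` sentinel; the ratio is
#' scale invariant, so any positive rescaling of the column gives the same
#' T2.
#'
#' @param column Positive numeric vector (one mixing-matrix column).
#' @param echo_times Echo times in ms, same length, >= 2.
#' @return T2 in ms (possibly `Inf`, or negative for an increasing column).
#' @export
t2_from_column <- function(column, echo_times) {
  column <- as.numeric(column)
  if (length(column) != length(echo_times) || length(column) < 2)
    stop("column and echo_times must have equal length >= 2")
  if (any(column <= 0)) stop("column entries must be positive")
  .t2_implied(column, as.numeric(echo_times))
}

# Nonnegative exponential b0-system solve shared by the exported wrapper and
# bss_voxel.
.fractions_core <- function(b0, te, t2) {
  E <- exp(outer(-te, 1 / t2))
  w <- tryCatch(pracma::lsqnonneg(E, b0)$x,
                error = function(e) pmax(qr.solve(E, b0), 0))
  s0 <- sum(w)
  if (s0 <= 0) stop("degenerate voxel: zero proton density")
  list(s0 = s0, f = w / s0)
}

#' Estimate proton density and volume fractions from b = 0 decays
#'
#' Solves the exponential system `E w = b0_signals`, with
#' `E_ji = exp(-TE_j / T2_i)`, by nonnegative least squares; the proton
#' density is `s0 = sum(w)` and the fractions `f = w / s0` (so they sum to
#' 1 by construction). Requires at least as many echo times as compartments
#' and pairwise-distinct T2 values; with more compartments than measurements
#' the system is undetermined.
#'
#' @param b0_signals Numeric vector of length N: the measured b = 0 signal
#'   at each echo time.
#' @param echo_times Echo times in ms (length N).
#' @param t2 Estimated T2 per compartment in ms (length M <= N), pairwise
#'   distinct; `Inf` entries are admitted (flat decay).
#' @return List with `s0` and `f`.
#' @export
estimate_fractions <- function(b0_signals, echo_times, t2) {
  b0_signals <- as.numeric(b0_signals); echo_times <- as.numeric(echo_times)
  t2 <- as.numeric(t2)
  if (length(b0_signals) != length(echo_times))
    stop("b0_signals and echo_times must have equal length")
  if (length(t2) > length(echo_times))
    stop("more compartments than echo times: system undetermined")
  if (anyDuplicated(t2)) stop("t2 values must be pairwise distinct")
  .fractions_core(b0_signals, echo_times, t2)
}

#' Recover the source matrix from the physical mixing matrix
#'
#' Inverts the rebuilt mixing matrix: `S = (s0 * A_real)^-1 X` (Moore-Penrose
#' pseudo-inverse when M < N). Rows of compartments with a fixed diffusion
#' prior are re-imposed. A condition number of `A_real` above `cond_warn`
#' flags the result, but it is retained — the relative factorization error
#' is the per-voxel trust metric.
#'
#' @param A_real N x M mixing matrix containing `f_i * exp(-TE_j / T2_i)`
#'   (no proton density).
#' @param s0 Proton-density scale.
#' @param X N x n signal matrix.
#' @param config Optional `bss_solver_config`; when given, fixed-source rows
#'   are re-imposed using `scheme`.
#' @param scheme Optional `bss_scheme` (required with `config`).
#' @param cond_warn Condition-number threshold for the instability flag
#'   (default 1e3).
#' @return M x n source matrix with attribute `"ill_conditioned"`.
#' @export
recover_sources <- function(A_real, s0, X, config = NULL, scheme = NULL,
                            cond_warn = 1e3) {
  A_real <- as.matrix(A_real); X <- as.matrix(X)
  As <- s0 * A_real
  kap <- kappa(As, exact = TRUE)
  S <- if (nrow(As) == ncol(As)) {
    tryCatch(solve(As, X), error = function(e)
      stop("singular mixing matrix: are the compartment T2 values distinct?"))
  } else {
    pracma::pinv(As) %*% X
  }
  if (!is.null(config)) {
    stopifnot(!is.null(scheme))
    dg <- .digest_config(config, scheme)
    for (i in which(dg$has_fix)) S[i, ] <- dg$Sfix[[i]]
  }
  attr(S, "ill_conditioned") <- kap > cond_warn
  attr(S, "cond_A") <- kap
  S
}

#' Relative factorization error
#'
#' `epsilon = ||X - s0 * A_real %*% S||_F / ||X||_F`, the per-voxel quality
#' metric of the factorization: it is sensitive both to violations of the
#' shared-source assumption across echo times and to error amplification by
#' an ill-conditioned mixing matrix.
#'
#' @param X N x n signal matrix (nonzero).
#' @param s0 Proton density.
#' @param A_real N x M mixing matrix with the `f * exp` terms.
#' @param S M x n source matrix.
#' @return Nonnegative scalar; invariant to global rescaling of the voxel.
#' @export
factorization_error <- function(X, s0, A_real, S) {
  X <- as.matrix(X)
  nx <- sqrt(sum(X^2))
  if (nx == 0) stop("degenerate voxel: ||X|| = 0")
  sqrt(sum((X - s0 * (as.matrix(A_real) %*% as.matrix(S)))^2)) / nx
}

#' Count compartments supported by the estimated fractions
#'
#' @param f Volume fractions summing to 1.
#' @param threshold Minimum fraction for a compartment to count
#'   (default 0.05).
#' @return Integer number of compartments with `f_i >= threshold`.
#' @export
count_compartments <- function(f, threshold = 0.05) {
  sum(f >= threshold)
}

# Full per-voxel estimation on bare matrices; t2_cap replaces the +Inf
# sentinel when reporting maps.
.bss_voxel_core <- function(X, te, b0_idx, dg, max_iter, tol, floor_,
                            count_threshold = 0.05) {
  fac <- .cals_core(X, te, b0_idx, dg, max_iter, tol, floor_)
  M <- dg$M
  t2 <- numeric(M)
  for (i in seq_len(M)) {
    t2[i] <- if (dg$fixed[i]) dg$ctr[i] else {
      v <- .t2_implied(fac$A[, i], te)
      if (is.na(v)) dg$ctr[i] else v
    }
  }
  # map the flat-column sentinel to the compartment's upper bound, and keep
  # the exponential system solvable when two estimates collide
  t2r <- ifelse(is.finite(t2), t2, dg$hi)
  if (anyDuplicated(t2r)) t2r <- t2r + (seq_len(M) - 1) * 1e-9
  b0 <- rowMeans(X[, b0_idx, drop = FALSE])
  fr <- .fractions_core(b0, te, t2r)
  A_real <- exp(outer(-te, 1 / t2r))
  A_real <- A_real * rep(fr$f, each = length(te))
  As <- fr$s0 * A_real
  kap <- kappa(A_real, exact = TRUE)
  S <- if (nrow(As) == ncol(As) && all(fr$f > 0)) {
    tryCatch(solve(As, X), error = function(e) pracma::pinv(As) %*% X)
  } else {
    # zero fractions make A_real rank deficient; fall back to pseudo-inverse
    pracma::pinv(As) %*% X
  }
  for (i in which(dg$has_fix)) S[i, ] <- dg$Sfix[[i]]
  eps <- sqrt(sum((X - As %*% S)^2)) / sqrt(sum(X^2))
  list(s0 = fr$s0, f = fr$f, t2 = t2r, A_real = A_real, S = S,
       epsilon = eps, n_compartments = sum(fr$f >= count_threshold),
       cond_A = kap, n_iter = fac$n_iter, converged = fac$converged)
}

#' Full blind-source-separation estimation for one voxel
#'
#' Composition of the whole per-voxel method: constrained ALS factorization,
#' T2 read-out from the mixing-matrix columns, nonnegative solve for the
#' volume fractions and proton density from the b = 0 decays, rebuild of the
#' physical mixing matrix `A_real` (elements `f_i * exp(-TE_j / T2_i)`),
#' source recovery by inversion, relative factorization error, and the
#' supported-compartment count.
#'
#' @param X N x n nonnegative signal matrix of one voxel.
#' @param scheme A `bss_scheme`.
#' @param config A `bss_solver_config` (M <= N).
#' @param count_threshold Fraction threshold for [count_compartments()]
#'   (default 0.05).
#' @return Object of class `bss_result`: list with `s0`, `f`, `t2` (ms;
#'   flat-decay columns reported at their upper bound), `A_real`, `S`,
#'   `epsilon`, `n_compartments`, `cond_A`, `n_iter`, `converged`.
#' @examples
#' sch <- sim_scheme(c(75.1, 135.1))
#' cfg <- solver_config(list(
#'   compartment("IE", t2_bounds = c(0, 200)),
#'   compartment("CSF", t2_fixed = 2000, fixed_source_adc = 3e-3)))
#' tp <- tissue_params(1, c(0.5, 0.5), c(80, 2000))
#' set.seed(1)
#' S <- synthesize_sources(sch, list(gaussian_source_spec(0.7e-3, 0.3e-3),
#'                                   gaussian_source_spec(3e-3, 0.1e-3)))
#' res <- bss_voxel(mix_signal(tp, S, sch), sch, cfg)
#' round(res$f, 3)
#' @export
bss_voxel <- function(X, scheme, config, count_threshold = 0.05) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative")
  if (all(X == 0)) stop("all-zero signal (background voxel)")
  dg <- .digest_config(config, scheme)
  if (dg$M > scheme$n_te)
    stop("more compartments than echo times (M > N)")
  out <- .bss_voxel_core(X, scheme$echo_times, scheme$b0_idx, dg,
                         config$max_iter, config$tol, config$nonneg_floor,
                         count_threshold)
  class(out) <- "bss_result"
  out
}

#' @export
print.bss_result <- function(x, ...) {
  cat("BSS voxel estimate\n")
  cat(sprintf("  s0 = %.4g; f = %s; T2 (ms) = %s\n", x$s0,
              paste(sprintf("%.3f", x$f), collapse = ", "),
              paste(signif(x$t2, 4), collapse = ", ")))
  cat(sprintf("  epsilon = %.3e; %d compartment(s); cond(A) = %.3g\n",
              x$epsilon, x$n_compartments, x$cond_A))
  invisible(x)
}
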