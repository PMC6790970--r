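#' Solver configuration for the constrained ALS factorization
#'
#' @param compartments List of [compartment()] objects, one per expected
#'   compartment (length M). Their order is preserved: compartment identity
#'   is carried by the configured constraints, so no relabeling is done.
#' @param max_iter Maximum number of alternating iterations (default 500).
#' @param tol Relative change of the Frobenius objective below which the
#'   iteration stops (default 1e-8).
#' @param nonneg_floor Value to which negative entries are clipped
#'   (default 0).
#' @return An object of class `bss_solver_config`.
#' @export
solver_config <- function(compartments, max_iter = 500, tol = 1e-8,
                          nonneg_floor = 0) {
  if (inherits(compartments, "bss_compartment")) compartments <- list(compartments)
  stopifnot(length(compartments) >= 1,
            all(vapply(compartments, inherits, TRUE, "bss_compartment")))
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  if (nonneg_floor < 0) stop("nonneg_floor must be >= 0")
  structure(list(compartments = compartments, max_iter = max_iter,
                 tol = tol, nonneg_floor = nonneg_floor),
            class = "bss_solver_config")
}

# Pre-digest the compartment constraints into flat vectors for the inner
# loop: lo/hi bounds (fixed T2 -> degenerate interval), center T2, and the
# fixed source rows evaluated on the scheme's b-values.
.digest_config <- function(config, scheme) {
  comps <- config$compartments
  M <- length(comps)
  lo <- hi <- ctr <- numeric(M)
  fixed <- logical(M)
  Sfix <- vector("list", M)
  for (i in seq_len(M)) {
    cp <- comps[[i]]
    if (!is.null(cp$t2_fixed)) {
      lo[i] <- hi[i] <- ctr[i] <- cp$t2_fixed
      fixed[i] <- TRUE
    } else {
      lo[i] <- cp$t2_bounds[1]; hi[i] <- cp$t2_bounds[2]
      ctr[i] <- mean(cp$t2_bounds)
    }
    if (!is.null(cp$fixed_source_adc)) {
      row <- exp(-scheme$bvals * cp$fixed_source_adc)
      row[scheme$b0_idx] <- 1
      Sfix[[i]] <- row
    }
  }
  list(M = M, lo = lo, hi = hi, ctr = ctr, fixed = fixed, Sfix = Sfix,
       has_fix = !vapply(Sfix, is.null, TRUE))
}

# T2 implied by one mixing-matrix column: the log-ratio slope over the
# leading (shortest-TE) pair of positive entries. Entries at longer echoes
# are ignored deliberately: a fast-decaying compartment's column underflows
# there to the clipping floor plus leakage, and letting those entries into
# the slope destabilizes the alternating iteration. Nonpositive entries are
# skipped; fewer than two positive entries -> NA (degenerate column).
# Returns +Inf for a flat pair and a negative value for an increasing one.
.t2_implied <- function(column, te) {
  pos <- which(column > 0)
  if (length(pos) < 2) return(NA_real_)
  k <- pos[1]; l <- pos[2]
  d <- log(column[k]) - log(column[l])
  if (abs(d) < 1e-12) return(Inf)
  (te[l] - te[k]) / d
}

#' Initialize the mixing matrix at the center of the T2 constraints
#'
#' Column i is `exp(-TE_j / T2c_i)` with T2c the midpoint of the
#' compartment's bounds (or its fixed value). Deterministic by design: the
#' solver never uses random initialization.
#'
#' @param scheme A `bss_scheme`.
#' @param config A `bss_solver_config`.
#' @return N x M mixing matrix.
#' @export
initialize_mixing <- function(scheme, config) {
  ctr <- vapply(config$compartments, .t2_center, 0)
  exp(outer(-scheme$echo_times, 1 / ctr))
}

# Project the columns of A into their T2-feasible sets (bare-matrix core).
.project_cols <- function(A, te, dg) {
  for (i in seq_len(dg$M)) {
    col <- A[, i]
    a1 <- if (col[1] > 0) col[1] else max(col, 1e-12)
    if (dg$fixed[i]) {
      # pinned T2: always reset the decay direction, keep the leading scale
      A[, i] <- a1 * exp(-(te - te[1]) / dg$ctr[i])
      next
    }
    t2 <- .t2_implied(col, te)
    bad <- is.na(t2) || t2 <= dg$lo[i] || t2 > dg$hi[i]
    t2c <- if (bad) dg$ctr[i] else t2
    # rebuild the column as an exact exponential at the accepted T2: the
    # relaxometry structure of A is what identifies the factors when M = N
    # (for N = 2 any positive column is already exponential, so in-bounds
    # columns pass through unchanged)
    A[, i] <- a1 * exp(-(te - te[1]) / t2c)
  }
  A
}

#' Project mixing-matrix columns back into their T2 bounds
#'
#' For each column the implied T2 (the log-ratio slope over the leading pair
#' of positive entries) is checked against the compartment's bounds; columns
#' falling outside — including degenerate columns whose entries are not all
#' positive — are replaced by the center-of-bounds exponential, preserving
#' the column's leading scale. Fixed-T2 columns are always reset to their
#' exact exponential direction.
#'
#' @param A N x M nonnegative mixing matrix.
#' @param scheme A `bss_scheme`.
#' @param config A `bss_solver_config`.
#' @return Projected N x M matrix; every column implies an in-bounds T2.
#' @export
project_t2_constraints <- function(A, scheme, config) {
  .project_cols(as.matrix(A), scheme$echo_times, .digest_config(config, scheme))
}

# Evaluate the constrained factorization at a fixed T2 vector: the sources
# are the exact least-squares solution given the exponential basis E(tau)
# (variable projection), rescaled so each row has unit b = 0 signal, with
# fixed-source rows pinned to their prior and negatives clipped. Returns the
# factors and the squared residual ||X - A S||^2, which measures constraint
# violation (and LS misfit when M < N): it vanishes only where the T2s,
# sources and priors are mutually consistent.
.vp_eval <- function(tau, X, te, b0_idx, dg, floor_) {
  E <- exp(outer(-te, 1 / tau))
  S <- if (length(tau) == nrow(X)) {
    tryCatch(solve(E, X), error = function(e) NULL)
  } else {
    tryCatch(solve(crossprod(E), crossprod(E, X)), error = function(e) NULL)
  }
  if (is.null(S))
    return(list(resid = sum(X^2) * 10 + 1, A = E, S = NULL, singular = TRUE))
  cc <- rowMeans(S[, b0_idx, drop = FALSE])
  dead <- cc <= 1e-12          # compartment absent (or sign-flipped): drop it
  cc[dead] <- 0
  live <- which(!dead)
  S[live, ] <- S[live, , drop = FALSE] / cc[live]
  if (any(dead)) S[which(dead), ] <- 0
  for (i in which(dg$has_fix)) S[i, ] <- dg$Sfix[[i]]
  S[S < floor_] <- floor_
  A <- E * rep(cc, each = length(te))
  resid <- sum((X - A %*% S)^2)
  # physical feasibility: the implied proton density sum(cc) extrapolates the
  # b = 0 signal back to TE = 0 and cannot exceed the strongest measurement
  # by more than a modest decay factor; without this cap a near-zero T2
  # column can fit the shortest echo exactly with an absurd scale
  s0_cap <- 5 * max(X[1, b0_idx])
  s0_hat <- sum(cc)
  if (s0_hat > s0_cap) resid <- resid + sum(X^2) * (s0_hat / s0_cap)
  list(resid = resid, A = A, S = S, singular = FALSE)
}

# T2 search grid of one free compartment: geometric spacing across the
# bounds, always including the center. The lower end is floored at the
# identifiability limit: a compartment whose signal has decayed below ~1% by
# the second echo leaves no slope information (the T2 read-out needs two visible
# echoes), and admitting such T2s lets a column degenerate into a
# first-echo-only noise sink. The floor never exceeds the interval center.
.tau_grid <- function(lo, hi, ctr, n, vis_floor = 0) {
  lo <- max(lo, 0.01 * hi, 1e-2, min(vis_floor, ctr))
  lo <- min(lo, hi * 0.99)
  g <- exp(seq(log(lo * 1.0001), log(hi), length.out = n))
  sort(unique(c(g, ctr)))
}

# Bare-matrix solver core shared by the exported wrapper and the Monte-Carlo
# loops. Minimizes the variable-projection residual over the free T2s:
# coarse grid scan (anchored at the constraint centers) followed by cyclic
# bounded line searches until the relative objective change drops below tol.
.cals_core <- function(X, te, b0_idx, dg, max_iter, tol, floor_) {
  free <- which(!dg$fixed)
  tau <- dg$ctr
  phi <- function(tv) .vp_eval(tv, X, te, b0_idx, dg, floor_)$resid
  n_eval_grid <- c(25L, 11L, 7L)
  trace <- numeric(0)
  converged <- TRUE
  vis_floor <- if (length(te) >= 2) te[2] / log(100) else 0
  if (length(free) > 0) {
    ## grid scan over the free T2s
    ng <- n_eval_grid[min(length(free), 3L)]
    grids <- lapply(free, function(i)
      .tau_grid(dg$lo[i], dg$hi[i], dg$ctr[i], ng, vis_floor))
    cells <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    best <- Inf; best_tau <- tau
    for (k in seq_len(nrow(cells))) {
      tv <- tau; tv[free] <- cells[k, ]
      r <- phi(tv)
      if (r < best) { best <- r; best_tau <- tv }
    }
    tau <- best_tau
    ratio <- vapply(grids, function(g)
      exp(diff(range(log(g))) / (length(g) - 1)), 0)
    names(ratio) <- as.character(free)
    ## local refinement: cyclic line searches within one grid cell's reach;
    ## a dozen sweeps bound the T2s to well below the line-search tolerance,
    ## so further objective creep does not move the estimates
    obj_prev <- best
    converged <- FALSE
    for (it in seq_len(min(max_iter, 12L))) {
      for (i in free) {
        rt <- ratio[[as.character(i)]]
        lo_i <- max(dg$lo[i], 0.01 * dg$hi[i], 1e-2,
                    min(vis_floor, dg$ctr[i]), tau[i] / rt^2)
        hi_i <- min(dg$hi[i], max(tau[i] * rt^2, lo_i * 1.0001))
        f1 <- function(t) { tv <- tau; tv[i] <- t; phi(tv) }
        tau[i] <- stats::optimize(f1, c(lo_i, hi_i),
                                  tol = max(1e-4, 2e-3 * tau[i]))$minimum
      }
      obj <- phi(tau)
      trace <- c(trace, sqrt(obj))
      if (obj <= 1e-14 * sum(X^2) ||   # exact fit: nothing left to refine
          abs(obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    # one tight polishing sweep so exact factorizations reach machine-level
    # residuals
    for (i in free) {
      rt <- ratio[[as.character(i)]]
      lo_i <- max(dg$lo[i], 0.01 * dg$hi[i], 1e-2,
                  min(vis_floor, dg$ctr[i]), tau[i] / rt)
      hi_i <- min(dg$hi[i], max(tau[i] * rt, lo_i * 1.0001))
      f1 <- function(t) { tv <- tau; tv[i] <- t; phi(tv) }
      tau[i] <- stats::optimize(f1, c(lo_i, hi_i),
                                tol = 1e-6 * max(tau[i], 1))$minimum
    }
    obj <- phi(tau)
    trace <- c(trace, sqrt(obj))
    # out-of-bounds rule: an estimate pressed against either end of its
    # admissible interval means the unconstrained optimum lies outside (or,
    # at the visibility floor, that the column carries no usable slope at
    # the second echo); such columns are set back to the center of their
    # constrained space
    for (k in seq_along(free)) {
      i <- free[k]
      lo_eff <- grids[[k]][1]
      pegged_lo <- tau[i] <= lo_eff * 1.05 && dg$ctr[i] > lo_eff
      pegged_hi <- tau[i] >= dg$hi[i] * 0.99 && dg$ctr[i] < dg$hi[i] * 0.99
      if (pegged_lo || pegged_hi) tau[i] <- dg$ctr[i]
    }
  }
  fin <- .vp_eval(tau, X, te, b0_idx, dg, floor_)
  if (length(trace) == 0) trace <- sqrt(fin$resid)
  list(A = fin$A, S = fin$S, n_iter = max(length(trace), 1L),
       converged = converged, objective_trace = trace,
       singular = fin$singular)
}

#' Constrained least-squares factorization of a multi-TE signal matrix
#'
#' Factorizes the nonnegative N x n multi-TE signal matrix `X` into a
#' mixing matrix `A` (N x M) whose columns are exponentials in the echo
#' times, and a source matrix `S` (M x n), under the physical constraints
#' of the compartment model: each column's T2 must lie inside its
#' compartment's bounds, source rows are nonnegative with unit b = 0
#' signal, and rows of compartments with a known diffusivity are pinned to
#' exp(-b * D).
#'
#' The two least-squares subproblems of the alternation are solved by
#' variable projection: for a candidate T2 vector the sources are the exact
#' least-squares solution given the exponential basis (clipped, pinned and
#' renormalized), so the residual is a function of the bounded T2s alone.
#' That residual is minimized deterministically — a geometric grid scan
#' anchored at the central T2 of each constraint, followed by cyclic line
#' searches — avoiding random initializations. Two safeguards handle
#' degenerate geometry: the T2 search is floored where a compartment's
#' signal would have decayed below ~1% by the second echo (no slope
#' information exists there), and the implied proton density is capped at a
#' small multiple of the strongest measurement. Estimates pressed against
#' either end of their admissible interval are set back to the center of
#' the constrained space.
#'
#' The returned `A` is scale-ambiguous: its column norms do not carry the
#' volume fractions. Use [bss_voxel()] for the full physical-parameter
#' estimation.
#'
#' @param X N x n nonnegative signal matrix (rows = echo times), or a matrix
#'   with attribute conventions produced by [mix_signal()].
#' @param scheme A `bss_scheme` (supplies echo times and b = 0 columns).
#' @param config A `bss_solver_config` with M <= N compartments.
#' @return List of class `bss_factorization` with elements `A`, `S`,
#'   `n_iter`, `converged`, `objective_trace` and `singular` (TRUE when a
#'   ridge fallback was needed).
#' @export
cals_factorize <- function(X, scheme, config) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative")
  if (all(X == 0)) stop("all-zero signal (background voxel)")
  if (nrow(X) != scheme$n_te || ncol(X) != scheme$n_meas)
    stop("X shape does not match the scheme")
  dg <- .digest_config(config, scheme)
  if (dg$M > scheme$n_te)
    stop("more compartments than echo times (M > N): factorization undetermined")
  out <- .cals_core(X, scheme$echo_times, scheme$b0_idx, dg,
                    config$max_iter, config$tol, config$nonneg_floor)
  class(out) <- "bss_factorization"
  out
}

#' @export
print.bss_factorization <- function(x, ...) {
  cat(sprintf("cALS factorization: %d compartments, %d iterations (%s)\n",
              ncol(x$A), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective ||X - AS||_F = %.3e\n",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
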