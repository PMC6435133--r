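.fro <- function(M) sqrt(sum(M^2))

# Thin SVD, exact; routed through eigen(crossprod) for large tall problems
# where LAPACK's full bidiagonalization is needlessly expensive.  Both
# routes agree to high accuracy for the well-conditioned sign matrices
# handled here (checked in the test suite at 1e-8).
.svd_auto <- function(M, size_switch = 2e5) {
  M <- as.matrix(M)
  if (length(M) <= size_switch || nrow(M) < ncol(M)) {
    return(svd(M))
  }
  C <- crossprod(M)                 # l x l symmetric
  e <- eigen(C, symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  v <- e$vectors
  pos <- d > max(d[1], 1e-300) * 1e-12
  u <- matrix(0, nrow(M), ncol(M))
  if (any(pos))
    u[, pos] <- (M %*% v[, pos, drop = FALSE]) /
      rep(d[pos], each = nrow(M))
  list(d = d, u = u, v = v)
}

#' Singular value shrinkage (soft-thresholding) operator
#'
#' Applies `D_tau`: compute the SVD `M = U diag(sigma) V^T` and replace
#' every singular value by `max(sigma - tau, 0)`.  This is the proximal
#' operator of `tau * ||.||_*`, i.e. the unique minimizer of
#' `0.5 ||M - Z||_F^2 + tau ||Z||_*`.
#'
#' @param M a numeric matrix
#' @param tau shrinkage threshold, `>= 0`, in singular-value units
#' @return the shrunk matrix
#' @examples
#' shrink_singular_values(diag(c(3, 1)), tau = 2)   # diag(1, 0)
#' @export
shrink_singular_values <- function(M, tau) {
  stopifnot(tau >= 0)
  s <- .svd_auto(M)
  d <- pmax(s$d - tau, 0)
  keep <- which(d > 0)
  if (!length(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Complete a read matrix by singular value thresholding (SVT)
#'
#' Iterates, from `Y^0 = R`,
#' `X^k = D_tau(Y^{k-1})` and `Y^k = Y^{k-1} + delta * P_Omega(R - X^k)`,
#' until the relative observed residual
#' `||P_Omega(X^k - R)||_F <= eps * ||R||_F` or `max_iter` sweeps.
#' `P_Omega` keeps observed cells and zeroes the rest, so only observed
#' cells of `Y` are ever corrected.
#'
#' @param rm a [read_matrix] with at least one observed cell
#' @param tau shrinkage threshold; default `5 * sqrt(N * l)`
#' @param delta step size; default `min(1.2 * N * l / |Omega|, 1.9)`.  The
#'   fixed-point iteration on the observed cells is only stable for
#'   `delta < 2` (the shrinkage operator is 1-Lipschitz), so the usual
#'   `1.2 / sampling-ratio` heuristic is capped at 1.9 for densely
#'   sampled matrices.
#' @param eps relative residual tolerance in (0, 1)
#' @param max_iter iteration cap
#' @return the completed `N x l` matrix (last `X^k`), with attribute
#'   `"diagnostics"`: list with `iterations`, `residual` (final relative
#'   residual), `residual_trace` and `converged`.  Non-convergence is
#'   flagged, not an error.
#' @export
complete_svt <- function(rm, tau = NULL, delta = NULL, eps = 1e-4,
                         max_iter = 500L) {
  N <- rm$n_reads; l <- rm$n_sites
  nobs <- n_observed(rm)
  if (nobs == 0L) stop("cannot complete a matrix with no observed cells")
  stopifnot(eps > 0, eps < 1, max_iter >= 1L)
  if (is.null(tau)) tau <- 5 * sqrt(N * l)
  if (is.null(delta)) delta <- min(1.2 * N * l / nobs, 1.9)
  stopifnot(tau > 0, delta > 0)
  R <- as_dense(rm)
  obs <- observed_cells(rm)
  idx <- obs$i + (obs$j - 1L) * N
  r_obs <- obs$x
  normR <- .fro(R)
  Y <- R
  X <- matrix(0, N, l)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(max_iter)) {
    iters <- k
    X <- shrink_singular_values(Y, tau)
    resid <- sqrt(sum((X[idx] - r_obs)^2)) / normR
    trace <- c(trace, resid)
    if (resid <= eps) { converged <- TRUE; break }
    Y[idx] <- Y[idx] + delta * (r_obs - X[idx])
  }
  if (!converged)
    warning("SVT did not reach the residual tolerance in ", max_iter,
            " iterations (final relative residual ",
            signif(trace[length(trace)], 3), ")")
  attr(X, "diagnostics") <- list(solver = "svt", iterations = iters,
                                 residual = trace[length(trace)],
                                 residual_trace = trace,
                                 converged = converged,
                                 tau = tau, delta = delta)
  X
}

# projection onto {Z : ||P_Omega(Z) - r_obs||_F <= eps}, acting on the
# observed cells only
.project_ball <- function(Z, idx, r_obs, eps) {
  d <- Z[idx] - r_obs
  nd <- sqrt(sum(d^2))
  if (nd > eps) Z[idx] <- r_obs + d * (eps / nd)
  Z
}

#' Complete a read matrix by nuclear-norm minimization
#'
#' Solves the convex program
#' `min ||H||_*  subject to  ||P_Omega(H - R)||_F <= eps`
#' (the nuclear norm, the sum of singular values, is the convex surrogate
#' of rank).  The program is solved by Douglas-Rachford splitting: the
#' proximal step of the nuclear norm is [shrink_singular_values()] and the
#' projection onto the constraint ball is closed-form on the observed
#' cells.  The returned point satisfies the constraint exactly.
#'
#' @param rm a [read_matrix] with at least one observed cell
#' @param eps constraint radius (absolute, Frobenius units); default
#'   `1e-3 * ||R||_F`, appropriate for (near-)noiseless interpolation.
#'   For noisy data set `eps` near the expected noise norm on Omega.
#' @param gamma proximal scaling of the splitting; default
#'   `||R||_F / sqrt(min(N, l))` (the scale of a typical singular value)
#' @param max_iter iteration cap
#' @param tol relative fixed-point tolerance
#' @param size_cap maximum `N * l` accepted; per-iteration SVDs make the
#'   solver expensive, run it per block for larger inputs
#' @return the completed matrix with a `"diagnostics"` attribute
#'   (`iterations`, `converged`, `gap`)
#' @export
complete_nuclear <- function(rm, eps = NULL, gamma = NULL, max_iter = 2000L,
                             tol = 1e-7, size_cap = 4e5) {
  N <- rm$n_reads; l <- rm$n_sites
  nobs <- n_observed(rm)
  if (nobs == 0L) stop("cannot complete a matrix with no observed cells")
  if (N * l > size_cap)
    stop("problem size N*l = ", N * l, " exceeds the size cap (", size_cap,
         "); complete per haplotype block instead")
  R <- as_dense(rm)
  obs <- observed_cells(rm)
  idx <- obs$i + (obs$j - 1L) * N
  r_obs <- obs$x
  normR <- .fro(R)
  if (is.null(eps)) eps <- 1e-3 * normR
  if (is.null(gamma)) gamma <- normR / sqrt(min(N, l))
  stopifnot(eps >= 0, gamma > 0)
  Z <- R
  H <- R
  converged <- FALSE; iters <- 0L; gap <- NA_real_
  for (k in seq_len(max_iter)) {
    iters <- k
    H <- shrink_singular_values(Z, gamma)
    W <- .project_ball(2 * H - Z, idx, r_obs, eps)
    Z <- Z + W - H
    gap <- .fro(H - W) / max(1, .fro(H))
    if (gap < tol) { converged <- TRUE; break }
  }
  out <- .project_ball(H, idx, r_obs, eps)
  if (!converged)
    warning("nuclear-norm solver did not reach tolerance in ", max_iter,
            " iterations (fixed-point gap ", signif(gap, 3), ")")
  attr(out, "diagnostics") <- list(solver = "nuclear", iterations = iters,
                                   converged = converged, gap = gap,
                                   eps = eps, gamma = gamma)
  out
}

#' Trim over-observed rows and columns
#'
#' The first OPTSPACE step: columns whose degree (number of observed
#' entries) exceeds `2 |Omega| / l` are zeroed, and likewise rows with
#' degree above `2 |Omega| / N`.  Over-observed rows/columns would
#' otherwise dominate the spectral initialization.  Thresholds use the
#' input's |Omega|; the input is not modified.
#'
#' @param rm a [read_matrix]
#' @return a trimmed [read_matrix]; attributes `"trimmed_cols"` and
#'   `"trimmed_rows"` list what was zeroed
#' @export
trim_overobserved <- function(rm) {
  nobs <- n_observed(rm)
  if (nobs == 0L) return(rm)
  col_thr <- 2 * nobs / rm$n_sites
  row_thr <- 2 * nobs / rm$n_reads
  bad_col <- which(.col_degrees(rm) > col_thr)
  bad_row <- which(.row_degrees(rm) > row_thr)
  m <- rm$mat
  if (length(bad_col)) m[, bad_col] <- 0
  if (length(bad_row)) m[bad_row, ] <- 0
  out <- read_matrix(Matrix::drop0(m))
  attr(out, "trimmed_cols") <- bad_col
  attr(out, "trimmed_rows") <- bad_row
  out
}

#' Rank-r spectral projection (OPTSPACE initialization)
#'
#' Computes the top-`r` SVD of the (trimmed) read matrix and returns the
#' factor triple `(X, S, Y)` with `X = U`, `Y = V` and
#' `S = (N * l / |Omega|) * diag(sigma_1, ..., sigma_r)`; the rescaling
#' compensates for the subsampling of the observed entries so that
#' `X S Y^T` estimates the full matrix, not its zero-filled version.
#'
#' @param rm a [read_matrix] (typically trimmed), nonzero
#' @param r target rank (1 or 2 in the diploid model, but any `r >= 1`
#'   is accepted here)
#' @return list of class `factor_triple`: `X` (`N x r`, orthonormal
#'   columns), `S` (`r x r` diagonal), `Y` (`l x r`, orthonormal columns),
#'   `r`, and `padded` (TRUE when the matrix rank is below `r` and the
#'   missing factors were padded with zero singular values)
#' @export
project_rank_r <- function(rm, r) {
  stopifnot(r >= 1L)
  nobs <- n_observed(rm)
  if (nobs == 0L) stop("cannot project a matrix with no observed cells")
  N <- rm$n_reads; l <- rm$n_sites
  s <- .svd_auto(rm$mat)
  d <- s$d[seq_len(r)]
  padded <- any(d <= max(s$d[1], 1e-300) * 1e-10)
  X <- s$u[, seq_len(r), drop = FALSE]
  Y <- s$v[, seq_len(r), drop = FALSE]
  if (padded) {
    d[d < 0 | !is.finite(d)] <- 0
    X <- .complete_orthonormal(X)
    Y <- .complete_orthonormal(Y)
  }
  structure(list(X = X, S = diag(d, nrow = r) * (N * l / nobs), Y = Y,
                 r = as.integer(r), padded = padded),
            class = "factor_triple")
}

# replace (numerically) zero columns with an orthonormal completion
.complete_orthonormal <- function(U) {
  n <- nrow(U); r <- ncol(U)
  bad <- which(colSums(U^2) < 1e-12)
  if (!length(bad)) return(U)
  good <- setdiff(seq_len(r), bad)
  B <- U[, good, drop = FALSE]
  for (k in bad) {
    for (cand in seq_len(n)) {
      v <- numeric(n); v[cand] <- 1
      if (ncol(B)) v <- v - B %*% crossprod(B, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) { B <- cbind(B, v / nv); break }
    }
  }
  # restore order: good columns first as given, padded ones after
  out <- matrix(0, n, r)
  out[, good] <- U[, good]
  out[, bad] <- B[, ncol(B) - rev(seq_along(bad)) + 1L, drop = FALSE]
  out
}

# exact least-squares solve for the r x r core S given factors and
# observations; minimum-norm solution via SVD pseudoinverse so that
# rank-deficient designs (e.g. factors supported on disjoint components)
# stay bounded
.solve_core <- function(X, Y, obs, r) {
  A <- matrix(0, nrow(obs), r * r)
  for (b in seq_len(r))
    for (a in seq_len(r))
      A[, (b - 1L) * r + a] <- X[obs$i, a] * Y[obs$j, b]
  s <- svd(A)
  pos <- s$d > max(s$d[1], 1e-300) * 1e-10
  co <- s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], obs$x)) / s$d[pos])
  matrix(co, r, r)
}

.obj_factored <- function(X, S, Y, obs) {
  XS <- X %*% S
  pred <- rowSums(XS[obs$i, , drop = FALSE] * Y[obs$j, , drop = FALSE])
  sum((pred - obs$x)^2)
}

#' OPTSPACE cleaning: least-squares refinement of the factors
#'
#' Minimizes `sum over Omega of (R_ij - (X S Y^T)_ij)^2` where the inner
#' minimization over the `r x r` core `S` is solved exactly (linear least
#' squares on the observed cells) and the outer minimization over the
#' orthonormal factors is block-coordinate gradient descent: one
#' gradient step on `X`, then one on `Y`, each with backtracking step
#' halving, QR re-orthonormalization and an exact re-solve of `S`.
#' (Alternating the factors escapes saddle configurations a simultaneous
#' step can stall in.)  The objective trace is non-increasing by
#' construction: a step is only accepted if it lowers the objective.
#'
#' @param rm the [read_matrix] whose observed cells define the objective
#' @param init a `factor_triple` from [project_rank_r()]
#' @param max_iter outer iteration cap
#' @param tol stop when the relative objective decrease over an outer
#'   iteration falls below this
#' @return completed matrix `X S Y^T` with `"diagnostics"` attribute
#'   (`objective_trace`, `iterations`, `converged`, `stalled`)
#' @export
optspace_clean <- function(rm, init, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(init, "factor_triple"))
  N <- rm$n_reads; l <- rm$n_sites
  if (nrow(init$X) != N || nrow(init$Y) != l)
    stop("initialization factors are not conformable with the read matrix")
  r <- init$r
  obs <- observed_cells(rm)
  if (!nrow(obs)) stop("cannot clean a matrix with no observed cells")
  X <- init$X; Y <- init$Y
  S <- .solve_core(X, Y, obs, r)
  f <- .obj_factored(X, S, Y, obs)
  trace <- f
  step <- 1 / (1 + sum(S^2))
  converged <- FALSE; stalled <- FALSE; iters <- 0L
  slow <- 0L   # consecutive slow iterations; descent may crawl past a
               # saddle before accelerating again, so stopping needs
               # a few confirmations

  residual_mat <- function(X, S, Y) {
    pred <- rowSums((X %*% S)[obs$i, , drop = FALSE] *
                      Y[obs$j, , drop = FALSE])
    Matrix::sparseMatrix(i = obs$i, j = obs$j, x = pred - obs$x,
                         dims = c(N, l))
  }
  for (k in seq_len(max_iter)) {
    iters <- k
    if (f <= tol^2) { converged <- TRUE; break }
    f_start <- f
    # X step
    E <- residual_mat(X, S, Y)
    gX <- 2 * as.matrix(E %*% (Y %*% t(S)))
    st <- step * 2
    while (st > 1e-16) {
      Xn <- qr.Q(qr(X - st * gX))
      Sn <- .solve_core(Xn, Y, obs, r)
      fn <- .obj_factored(Xn, Sn, Y, obs)
      if (fn < f) { X <- Xn; S <- Sn; f <- fn; step <- st; break }
      st <- st / 2
    }
    # Y step
    E <- residual_mat(X, S, Y)
    gY <- 2 * as.matrix(Matrix::t(E) %*% (X %*% S))
    st <- step * 2
    while (st > 1e-16) {
      Yn <- qr.Q(qr(Y - st * gY))
      Sn <- .solve_core(X, Yn, obs, r)
      fn <- .obj_factored(X, Sn, Yn, obs)
      if (fn < f) { Y <- Yn; S <- Sn; f <- fn; step <- st; break }
      st <- st / 2
    }
    trace <- c(trace, f)
    if (f == f_start) {
      # no factor step could lower the objective
      gn <- sum(gX^2) + sum(as.matrix(gY)^2)
      if (gn <= 1e-20 * max(1, f)) converged <- TRUE else stalled <- TRUE
      break
    }
    if ((f_start - f) / max(f_start, 1e-300) < tol) {
      slow <- slow + 1L
      if (slow >= 3L) { converged <- TRUE; break }
    } else {
      slow <- 0L
    }
  }
  H <- X %*% S %*% t(Y)
  attr(H, "diagnostics") <- list(solver = "optspace", iterations = iters,
                                 objective = f, objective_trace = trace,
                                 converged = converged, stalled = stalled)
  attr(H, "factors") <- list(X = X, S = S, Y = Y)
  H
}

#' Complete a read matrix with the OPTSPACE scheme
#'
#' Composition of the three OPTSPACE steps: [trim_overobserved()] ->
#' [project_rank_r()] -> [optspace_clean()].  Trimming only shapes the
#' spectral initialization; by default the cleaning objective runs over
#' the original (untrimmed) observed cells, which is the objective the
#' model states on `R`.  Set `clean_on_trimmed = TRUE` to restrict the
#' cleaning objective to the trimmed cells instead.
#'
#' @param rm a [read_matrix]
#' @param r target rank, 1 (all-heterozygous haplotypes, `h_m = -h_p`) or
#'   2 (general diploid)
#' @param max_iter,tol passed to [optspace_clean()]
#' @param clean_on_trimmed see above
#' @return completed matrix with `"diagnostics"` attribute
#' @export
complete_optspace <- function(rm, r = 2L, max_iter = 200L, tol = 1e-6,
                              clean_on_trimmed = FALSE) {
  if (!r %in% c(1L, 2L))
    stop("rank must be 1 or 2 in the diploid model")
  if (n_observed(rm) == 0L)
    stop("cannot complete a matrix with no observed cells")
  trimmed <- trim_overobserved(rm)
  if (n_observed(trimmed) == 0L) trimmed <- rm  # degenerate: trim removed all
  init <- project_rank_r(trimmed, r)
  target <- if (clean_on_trimmed) trimmed else rm
  H <- optspace_clean(target, init, max_iter = max_iter, tol = tol)
  diag_ <- attr(H, "diagnostics")
  diag_$trimmed_cols <- attr(trimmed, "trimmed_cols")
  diag_$trimmed_rows <- attr(trimmed, "trimmed_rows")
  diag_$init_padded <- init$padded
  attr(H, "diagnostics") <- diag_
  H
}
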