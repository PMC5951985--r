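#' Initial factor of the inverse cross-spectral density
#'
#' Computes `B0`, the unique Hermitian positive-definite matrix square root
#' of the (optionally ridge-stabilized) inverse of a CSD slice, so that
#' `B0^H B0 = C^-1`. `B0` is the starting point of the unitary rotation
#' search: any factor of `C^-1` equals `U B0` for some unitary `U`.
#'
#' @param csd_slice `n x n` complex Hermitian positive-definite matrix.
#' @param ridge nonnegative ridge; `ridge * trace/n` times the identity is
#'   added to the slice before inversion. With `ridge = 0` a singular slice
#'   is an error (naming the smallest eigenvalue).
#' @param frequency optional frequency in Hz, carried as metadata.
#' @return An object of class `spectral_factor` with fields `b0`, `u` (NULL
#'   until optimized), `b` (NULL), `frequency`, `regularization`,
#'   `condition` (eigenvalue condition number of the stabilized slice),
#'   `cost_trace`, `converged`.
#' @export
initial_factor <- function(csd_slice, ridge = 0, frequency = NA_real_) {
  m <- as.matrix(csd_slice)
  if (nrow(m) != ncol(m)) stop("CSD slice must be square")
  herm_err <- max(Mod(m - Conj(t(m)))) / max(Mod(m), .Machine$double.xmin)
  if (herm_err > 1e-8)
    stop(sprintf("slice is not Hermitian (relative asymmetry %.2e)", herm_err))
  m <- (m + Conj(t(m))) / 2
  n <- nrow(m)
  if (ridge < 0) stop("`ridge` must be nonnegative")
  if (ridge > 0) m <- m + diag(ridge * Re(sum(diag(m))) / n, n)
  e <- eigen(m, symmetric = TRUE)
  lam <- e$values
  tol_sing <- n * .Machine$double.eps * max(lam)
  if (ridge == 0 && min(lam) <= tol_sing)
    stop(sprintf("CSD slice is singular (smallest eigenvalue %.3e); set a ridge",
                 min(lam)))
  if (min(lam) <= 0)
    stop(sprintf("slice still singular after ridge (smallest eigenvalue %.3e)",
                 min(lam)))
  V <- e$vectors
  b0 <- V %*% (t(Conj(V)) / sqrt(lam))  # V diag(lam^-1/2) V^H
  if (!is.complex(b0)) b0 <- matrix(as.complex(b0), n, n)
  structure(list(b0 = b0, u = NULL, b = NULL, frequency = frequency,
                 regularization = ridge, condition = max(lam) / min(lam),
                 cost_trace = NULL, converged = NA),
            class = "spectral_factor")
}

#' @export
print.spectral_factor <- function(x, ...) {
  cat(sprintf("spectral_factor: n = %d, frequency = %s Hz, %s\n",
              nrow(x$b0), format(x$frequency),
              if (is.null(x$u)) "not optimized" else
                sprintf("optimized (cost %.4g, converged: %s)",
                        utils::tail(x$cost_trace, 1), x$converged)))
  invisible(x)
}

#' Off-diagonal L1 norm
#'
#' Sum of complex moduli of the strictly off-diagonal entries: the sparsity
#' cost minimized over unitary rotations of the spectral factor.
#'
#' @param m square (complex) matrix.
#' @return Nonnegative scalar.
#' @export
offdiag_l1 <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  sum(Mod(m)) - sum(Mod(diag(m)))
}

random_unitary <- function(n) {
  z <- matrix(complex(real = stats::rnorm(n * n),
                      imaginary = stats::rnorm(n * n)) / sqrt(2), n, n)
  qr_z <- qr(z)
  Q <- qr.Q(qr_z)
  d <- diag(qr.R(qr_z))
  Q %*% diag(d / Mod(d), n)
}

#' Find the unitary rotation minimizing the off-diagonal L1 norm
#'
#' Riemannian conjugate-gradient descent on the unitary group for the
#' smoothed cost `sum_{i!=j} sqrt(|(U B0)_ij|^2 + eps)`. The Euclidean
#' gradient is projected onto the skew-Hermitian tangent space, updates move
#' along geodesics `U <- expm(-mu*G) U` with Armijo backtracking, and the
#' smoothing `eps` is annealed over `smoothing_schedule` with warm starts.
#' The search is repeated from `restarts` initializations (identity first,
#' then seeded random unitaries) and the lowest final un-smoothed cost wins.
#'
#' @param factor a `spectral_factor` from [initial_factor()].
#' @param max_iter iteration budget per start (across the whole schedule).
#' @param tol relative cost-change convergence tolerance.
#' @param smoothing_schedule decreasing eps values for the smoothed modulus.
#' @param restarts number of initializations (>= 1).
#' @param seed integer seed for the random restarts.
#' @param armijo_c Armijo sufficient-decrease constant.
#' @return The input factor with `u`, `b = u %*% b0`, `cost_trace` (smoothed
#'   cost at each accepted iterate), `final_cost` (un-smoothed off-diagonal
#'   L1), `converged` and `n_iter` filled in.
#' @export
optimize_unitary <- function(factor, max_iter = 2000L, tol = 1e-6,
                             smoothing_schedule = c(1e-2, 1e-4, 1e-6, 1e-8),
                             restarts = 3L, seed = NULL, armijo_c = 1e-4) {
  stopifnot(inherits(factor, "spectral_factor"))
  if (restarts < 1L) stop("`restarts` must be >= 1")
  if (any(diff(smoothing_schedule) > 0))
    stop("`smoothing_schedule` must be non-increasing")
  n <- nrow(factor$b0)
  starts <- c(list(diag(1 + 0i, n)),
              if (restarts > 1L) run_seeded(seed,
                replicate(restarts - 1L, random_unitary(n), simplify = FALSE)))
  best <- NULL
  for (U0 in starts) {
    res <- cpp_optimize_unitary(factor$b0, U0, smoothing_schedule,
                                as.integer(max_iter), tol, armijo_c)
    if (!all(is.finite(res$cost_trace)))
      stop("non-finite cost encountered during unitary optimization")
    if (is.null(best) || res$final_cost < best$final_cost) best <- res
  }
  if (!best$converged)
    warning("unitary optimization hit the iteration budget before converging")
  factor$u <- best$u
  factor$b <- best$u %*% factor$b0
  factor$cost_trace <- best$cost_trace
  factor$final_cost <- best$final_cost
  factor$converged <- best$converged
  factor$n_iter <- best$n_iter
  factor
}

#' Fix the residual row-phase ambiguity of the optimized factor
#'
#' After the rotation, the factor is still defined up to a diagonal unitary
#' (per-row phase). Each row is multiplied by the unit-modulus phase that
#' makes its diagonal entry real and positive; off-diagonal moduli (and thus
#' the L1 cost) are unchanged, and the operation is idempotent.
#'
#' @param b square complex matrix.
#' @return Matrix with real positive diagonal (rows with an exactly zero
#'   diagonal entry are left unchanged, with a warning).
#' @export
fix_phases <- function(b) {
  b <- as.matrix(b)
  d <- diag(b)
  zero <- Mod(d) == 0
  if (any(zero))
    warning(sprintf("zero diagonal entry in row(s) %s: phase left unchanged",
                    paste(which(zero), collapse = ", ")))
  ph <- ifelse(zero, 1 + 0i, Conj(d) / Mod(d))
  b * ph  # recycles column-wise: multiplies row i by ph[i]
}
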