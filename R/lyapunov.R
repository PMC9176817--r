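#' Lyapunov covariance dynamics
#'
#' Right-hand side of the continuous Lyapunov differential equation
#' `Pdot = A P + P A' + C Sigma C'` governing first-order covariance
#' propagation of a linearized stochastic system, with `Sigma` the
#' continuous-time PSD matrix of the disturbance sources.
#'
#' @param A closed-loop state Jacobian.
#' @param P symmetric state covariance.
#' @param C disturbance Jacobian (state_dim x noise_dim).
#' @param noise `noise_spec` (non-pinned sources, in the column order of `C`)
#'   or a PSD matrix.
#' @param sym_tol symmetry tolerance on `P` (default 1e-8).
#' @return symmetric `Pdot` matrix.
#' @export
lyapunov_rhs <- function(A, P, C, noise, sym_tol = 1e-8) {
  Sigma <- if (inherits(noise, "noise_spec")) psd_matrix(noise) else as.matrix(noise)
  P <- as.matrix(P)
  if (max(abs(re_part(P - t(P)))) > sym_tol)
    stop("lyapunov_rhs: P is not symmetric within tolerance")
  Pd <- A %*% P + P %*% t(A) + C %*% Sigma %*% t(C)
  (Pd + t(Pd)) / 2
}

#' Propagate a state covariance with explicit Euler steps
#'
#' Integrates `Pdot = A P + P A' + C Sigma C'` over `n_steps` steps of length
#' `dt`. `A` and `C` may be constant matrices or functions of time returning
#' the matrices at the step start. For linear time-invariant systems with
#' `A = 0` the result is exact and independent of `dt`.
#'
#' @param P0 initial covariance.
#' @param A,C constant matrices or functions `function(t)`.
#' @param noise `noise_spec` or PSD matrix.
#' @param dt step length (s).
#' @param n_steps number of steps.
#' @param keep return all intermediate covariances (list) instead of the final.
#' @return final covariance matrix, or list of matrices when `keep = TRUE`.
#' @export
propagate_covariance <- function(P0, A, C, noise, dt, n_steps, keep = FALSE) {
  Sigma <- if (inherits(noise, "noise_spec")) psd_matrix(noise) else as.matrix(noise)
  Afun <- if (is.function(A)) A else function(t) A
  Cfun <- if (is.function(C)) C else function(t) C
  P <- as.matrix(P0)
  out <- if (keep) vector("list", n_steps + 1L) else NULL
  if (keep) out[[1L]] <- P
  for (k in seq_len(n_steps)) {
    t_k <- (k - 1L) * dt
    Ak <- Afun(t_k); Ck <- Cfun(t_k)
    Pd <- Ak %*% P + P %*% t(Ak) + Ck %*% Sigma %*% t(Ck)
    P <- P + dt * (Pd + t(Pd)) / 2
    if (keep) out[[k + 1L]] <- P
  }
  if (keep) out else P
}

#' Stationary covariance from the algebraic Lyapunov equation
#'
#' Solves `A P + P A' + Q = 0` for symmetric `P` via the Kronecker-vectorized
#' linear system. `A` must be Hurwitz for the solution to be a valid
#' stationary covariance; stability is checked on `Re(A)` so the solve remains
#' complex-step differentiable.
#'
#' @param A square (Hurwitz) matrix.
#' @param Q symmetric positive semidefinite forcing (e.g. `C Sigma C'`).
#' @param check_stable error when `A` is not Hurwitz (default TRUE); when
#'   FALSE, returns `NULL` instead so callers can apply penalty branches.
#' @return symmetric stationary covariance, or `NULL` (see `check_stable`).
#' @export
lyapunov_stationary <- function(A, Q, check_stable = TRUE) {
  n <- nrow(A)
  ev <- eigen(re_part(A), only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-12) {
    if (check_stable) stop("lyapunov_stationary: A is not Hurwitz")
    return(NULL)
  }
  In <- diag(n)
  M <- kronecker(In, A) + kronecker(A, In)
  vecP <- solve(M, -as.vector(Q))
  P <- matrix(vecP, n, n)
  (P + t(P)) / 2
}

# max |P - P'| — symmetry defect, used by invariants/tests
symmetry_defect <- function(P) max(abs(P - t(P)))
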