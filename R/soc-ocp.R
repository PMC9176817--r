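#' Stochastic optimal control problem
#'
#' Bundles dynamics, noise, cost integrand, chance constraints and horizon
#' into a problem object that `soc_transcribe()` turns into a nonlinear
#' program. Two horizon kinds are supported: `"stationary"` (a single-node
#' algebraic formulation with `xdot_mean = 0` and `Pdot = 0`, used for quiet
#' and perturbed standing) and a finite horizon `c(t_start, t_final)` meshed
#' at `mesh_dt` (used for reaching; transcribed by the task-specific builder).
#'
#' @param dynamics `stochastic_dynamics`.
#' @param cost_integrand `function(x_mean, e_ff, K, P)` returning the scalar
#'   cost rate (expected effort unless a fixture overrides it).
#' @param ny dimension of the feedback signal.
#' @param constraints list of `chance_constraint`s.
#' @param horizon `"stationary"` or numeric `c(t_start, t_final)`.
#' @param mesh_dt mesh interval in seconds (default 0.01).
#' @param fixed_mean named numeric vector pinning mean-state entries by index
#'   (e.g. upright pendulum angle = 0).
#' @param mean_bounds optional 2 x n matrix of bounds for free mean entries.
#' @param pinned_states integer indices of states whose covariance block is
#'   imposed rather than solved (random-constant platform states).
#' @param pinned_cov covariance block for `pinned_states`.
#' @param K_mask logical m x ny matrix of free gain entries (e.g. vestibular
#'   columns forced to zero under vestibular loss); default all free.
#' @param e_ff_bounds excitation bounds on the mean (default c(0, 1)).
#' @param extra_eq optional `function(x_mean, e_ff, K)` of extra equalities.
#' @param sensory_cov_dt control interval used to discretize sensory PSDs in
#'   the effort/variance computations (default `mesh_dt`).
#' @param special marker consumed by task-specific transcription ("reach").
#' @param reference feedback reference passed to the policy (function of time
#'   or fixed vector), default NULL.
#' @param linearizer optional fast closed-loop linearization
#'   `function(x_mean, e_ff, K) -> list(A, C)` exploiting model structure;
#'   defaults to complex-step `linearize_closed_loop` and must agree with it.
#' @return object of class `stochastic_ocp`.
#' @export
stochastic_ocp <- function(dynamics, cost_integrand, ny,
                           constraints = list(),
                           horizon = "stationary", mesh_dt = 0.01,
                           fixed_mean = NULL, mean_bounds = NULL,
                           pinned_states = integer(0), pinned_cov = NULL,
                           K_mask = NULL, e_ff_bounds = c(0, 1),
                           extra_eq = NULL, sensory_cov_dt = NULL,
                           special = NULL, reference = NULL,
                           linearizer = NULL) {
  if (is.character(horizon)) {
    horizon <- match.arg(horizon, "stationary")
  } else if (length(horizon) != 2 ||
             diff(horizon) < 2 * mesh_dt) {
    stop("stochastic_ocp: finite horizon needs >= 2 mesh nodes")
  }
  if (is.null(K_mask))
    K_mask <- matrix(TRUE, dynamics$control_dim, ny)
  structure(list(dynamics = dynamics, cost_integrand = cost_integrand,
                 ny = as.integer(ny), constraints = constraints,
                 horizon = horizon, mesh_dt = mesh_dt,
                 fixed_mean = fixed_mean, mean_bounds = mean_bounds,
                 pinned_states = pinned_states, pinned_cov = pinned_cov,
                 K_mask = K_mask, e_ff_bounds = e_ff_bounds,
                 extra_eq = extra_eq,
                 sensory_cov_dt = if (is.null(sensory_cov_dt)) mesh_dt
                                  else sensory_cov_dt,
                 special = special, reference = reference,
                 linearizer = linearizer),
            class = "stochastic_ocp")
}

# Stationary closed-loop covariance with optional pinned (random-constant)
# state block: the cross block solves a linear system, the free block a
# 4x4-scale algebraic Lyapunov equation. Returns NULL when the free-block
# dynamics are not Hurwitz (callers apply a smooth penalty).
stationary_closed_loop_cov <- function(A, C, Sigma, pinned_states = integer(0),
                                       pinned_cov = NULL) {
  n <- nrow(A)
  Q <- C %*% Sigma %*% t(C)
  if (length(pinned_states) == 0L) {
    P <- lyapunov_stationary(A, Q, check_stable = FALSE)
    return(P)
  }
  ib <- setdiff(seq_len(n), pinned_states)
  Abb <- A[ib, ib, drop = FALSE]
  Abs <- A[ib, pinned_states, drop = FALSE]
  ev <- eigen(Abb, only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-12) return(NULL)
  Pss <- pinned_cov
  Pbs <- -solve(Abb, Abs %*% Pss)
  Qf <- Q[ib, ib, drop = FALSE] + Abs %*% t(Pbs) + Pbs %*% t(Abs)
  Pbb <- lyapunov_stationary(Abb, Qf, check_stable = FALSE)
  if (is.null(Pbb)) return(NULL)
  P <- matrix(0, n, n)
  P[ib, ib] <- Pbb
  P[ib, pinned_states] <- Pbs
  P[pinned_states, ib] <- t(Pbs)
  P[pinned_states, pinned_states] <- Pss
  (P + t(P)) / 2
}

#' Transcribe a stochastic OCP into a nonlinear program
#'
#' Stationary problems are transcribed in reduced space: the decision vector
#' holds the free mean-state entries, the feedforward excitations and the free
#' feedback-gain entries; the stationary covariance is eliminated exactly via
#' the algebraic Lyapunov equation (so the `Pdot = 0` defect is satisfied by
#' construction and `P` is symmetric by construction), mean stationarity
#' `f(x_mean) = 0` and any extra conditions become equality constraints, and
#' chance constraints become inequalities. Finite-horizon problems are
#' transcribed by their task-specific builders (see `build_reach_ocp`), which
#' attach a `transcribe` closure.
#'
#' @param ocp `stochastic_ocp`.
#' @return object of class `soc_nlp`: closures `objective`, `eq`, `ineq`,
#'   `make_PK` plus `z0`, bounds, `unpack`, and mesh metadata (`n_nodes`,
#'   `n_defects_eliminated`).
#' @export
soc_transcribe <- function(ocp) {
  if (!is.null(ocp$special) && !is.null(attr(ocp, "transcribe")))
    return(attr(ocp, "transcribe")(ocp))
  if (!identical(ocp$horizon, "stationary"))
    stop("soc_transcribe: finite-horizon transcription is attached by the task builder")
  dyn <- ocp$dynamics
  n <- dyn$state_dim; m <- dyn$control_dim; ny <- ocp$ny
  fixed_idx <- if (is.null(ocp$fixed_mean)) integer(0)
               else as.integer(names(ocp$fixed_mean))
  free_idx <- setdiff(seq_len(n), fixed_idx)
  kfree <- which(ocp$K_mask)
  nz <- length(free_idx) + m + length(kfree)
  Sigma <- psd_matrix(dyn$noise)

  unpack <- function(z) {
    x_mean <- numeric(n)
    if (length(fixed_idx)) x_mean[fixed_idx] <- as.numeric(ocp$fixed_mean)
    if (length(free_idx)) x_mean[free_idx] <- z[seq_along(free_idx)]
    e_ff <- z[length(free_idx) + seq_len(m)]
    K <- matrix(0, m, ny)
    K[kfree] <- z[length(free_idx) + m + seq_along(kfree)]
    list(x_mean = x_mean, e_ff = e_ff, K = K)
  }

  make_PK <- function(z) {
    u <- unpack(z)
    lin <- if (!is.null(ocp$linearizer)) {
      ocp$linearizer(u$x_mean, u$e_ff, u$K)
    } else {
      pol <- control_policy(u$e_ff, u$K, reference = ocp$reference)
      linearize_closed_loop(dyn, pol, u$x_mean)
    }
    P <- stationary_closed_loop_cov(lin$A, lin$C, Sigma,
                                    ocp$pinned_states, ocp$pinned_cov)
    c(u, list(P = P, A = lin$A, C = lin$C))
  }

  unstable_penalty <- function(A) {
    ib <- setdiff(seq_len(n), ocp$pinned_states)
    ev <- eigen(A[ib, ib, drop = FALSE], only.values = TRUE)$values
    1e6 + 1e5 * max(Re(ev))
  }

  objective <- function(z) {
    s <- make_PK(z)
    if (is.null(s$P)) return(unstable_penalty(s$A))
    ocp$cost_integrand(s$x_mean, s$e_ff, s$K, s$P)
  }

  eqfun <- function(z) {
    u <- unpack(z)
    pol <- control_policy(u$e_ff, u$K, reference = ocp$reference)
    f0 <- closed_loop_rhs(dyn, pol)(0, u$x_mean, numeric(dyn$noise_dim))
    out <- f0
    if (!is.null(ocp$extra_eq))
      out <- c(out, ocp$extra_eq(u$x_mean, u$e_ff, u$K))
    out
  }

  ineqfun <- if (length(ocp$constraints) == 0L) NULL else function(z) {
    s <- make_PK(z)
    if (is.null(s$P)) return(rep(1e3, length(ocp$constraints)))
    vapply(ocp$constraints, function(cc)
      -chance_constraint_value(cc, s$x_mean, s$P), numeric(1))
  }

  lower <- c(if (is.null(ocp$mean_bounds)) rep(-Inf, length(free_idx))
             else ocp$mean_bounds[1, free_idx],
             rep(ocp$e_ff_bounds[1], m), rep(-Inf, length(kfree)))
  upper <- c(if (is.null(ocp$mean_bounds)) rep(Inf, length(free_idx))
             else ocp$mean_bounds[2, free_idx],
             rep(ocp$e_ff_bounds[2], m), rep(Inf, length(kfree)))

  structure(list(objective = objective, eq = eqfun, ineq = ineqfun,
                 make_PK = make_PK, unpack = unpack,
                 z0 = numeric(nz), lower = lower, upper = upper,
                 n_nodes = 1L,
                 n_defects_eliminated = n * (n + 1L) / 2L,
                 free_idx = free_idx, kfree = kfree, ocp = ocp),
            class = "soc_nlp")
}

#' Solve a transcribed stochastic OCP
#'
#' Runs the augmented-Lagrangian solver on a `soc_nlp`. Non-convergence is
#' reported through the `status` field of the returned solution, never
#' silently accepted.
#'
#' @param nlp `soc_nlp` from `soc_transcribe`.
#' @param initial_guess optional decision vector overriding `nlp$z0` (for
#'   stationary problems, as produced by a previous warm solve).
#' @param solver_options control list passed to `al_minimize`.
#' @return `soc_solution` with policy, Gaussian trajectory, objective,
#'   status, and constraint residuals.
#' @export
soc_solve <- function(nlp, initial_guess = NULL, solver_options = list()) {
  if (!is.null(nlp$solve_fn))
    return(nlp$solve_fn(nlp, initial_guess, solver_options))
  z0 <- if (is.null(initial_guess)) nlp$z0 else initial_guess
  res <- al_minimize(nlp$objective, z0, eq = nlp$eq, ineq = nlp$ineq,
                     lower = nlp$lower, upper = nlp$upper,
                     control = solver_options)
  s <- nlp$make_PK(res$par)
  status <- res$status
  if (is.null(s$P)) status <- "unstable"
  pol <- control_policy(s$e_ff, s$K, reference = nlp$ocp$reference)
  traj <- if (!is.null(s$P))
    gaussian_trajectory(0, matrix(s$x_mean, 1), list(s$P)) else NULL
  soc_solution(policy = pol, trajectory = traj,
               objective_value = res$value, status = status,
               constraint_residuals = list(eq = res$eq, ineq = res$ineq,
                                           max_violation = res$max_violation),
               info = list(z = res$par, outer_iters = res$outer_iters,
                           A = s$A, C = s$C))
}
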