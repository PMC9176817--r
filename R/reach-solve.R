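# Two-stage reduced transcription of the finite-horizon reaching OCP.
#
# Stage A (mean + feedforward): the mean hand path is parameterized in task
# space (minimum-jerk profile plus a small smooth basis for timing and
# lateral deviation, all basis functions vanishing with zero slope at both
# ends so the boundary conditions -- start at rest, mean endpoint on target
# with zero velocity -- hold by construction). Inverse kinematics and inverse
# dynamics give the required joint torques; a per-node static optimization
# distributes them over the six muscles (min sum a^2, a >= 0); the exact
# inverse of the first-order activation dynamics yields the feedforward
# excitations e_ff = a + tau * da/dt. The mean-dynamics defects of the
# collocation formulation are therefore satisfied identically and the only
# stage-A decision variables are the handful of path coefficients.
#
# Stage B (covariance + gains): with the mean frozen, the closed-loop
# linearization A(t) + B K(t) H(t) is evaluated at the mesh nodes, the
# covariance is propagated by the discrete Lyapunov recursion
# P+ = Phi P Phi' + dt Q, and the time-varying gains (piecewise linear
# between coarse nodes) are optimized by an augmented-Lagrangian/BFGS loop
# with exact adjoint gradients. Accuracy constraints are bounds on the
# linear-propagated end-effector SDs.

minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
minjerk_d1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
minjerk_d2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

path_basis <- function(tau, j) sin(pi * tau) * sin(j * pi * tau)
path_basis_d1 <- function(tau, j)
  pi * cos(pi * tau) * sin(j * pi * tau) + j * pi * sin(pi * tau) * cos(j * pi * tau)
path_basis_d2 <- function(tau, j)
  -(1 + j^2) * pi^2 * sin(pi * tau) * sin(j * pi * tau) +
  2 * j * pi^2 * cos(pi * tau) * cos(j * pi * tau)

# minimal-norm non-negative static activations: min ||a||^2 s.t. W a = b
static_activations <- function(W, b) {
  free <- rep(TRUE, ncol(W))
  for (iter in seq_len(ncol(W))) {
    Wf <- W[, free, drop = FALSE]
    af <- tryCatch(t(Wf) %*% solve(Wf %*% t(Wf) + 1e-12 * diag(2), b),
                   error = function(e) NULL)
    if (is.null(af)) stop("static_activations: torque demand infeasible")
    if (all(af >= -1e-10)) {
      a <- numeric(ncol(W)); a[free] <- pmax(as.numeric(af), 0)
      return(a)
    }
    drop_i <- which(free)[which.min(af)]
    free[drop_i] <- FALSE
    if (!any(free)) stop("static_activations: torque demand infeasible")
  }
  stop("static_activations: active-set did not terminate")
}

# Mean trajectory, activations and feedforward excitations for given path
# coefficients theta = c(c_time (3), c_lat (3)).
reach_mean_trajectory <- function(theta, task, params, n_nodes = NULL) {
  arm <- params$arm
  gt <- reach_geom_tables(params)
  curves <- params$curves
  dt <- params$mesh_dt
  Tf <- task$duration
  if (is.null(n_nodes)) n_nodes <- round(Tf / dt) + 1L
  times <- seq(0, Tf, length.out = n_nodes)
  tau <- times / Tf
  ct <- theta[1:3]; cl <- theta[4:6]
  if (task$kind == "obstacle") cl <- c(0, 0, 0)   # hand stays on the line

  s <- minjerk(tau); s1 <- minjerk_d1(tau) / Tf; s2 <- minjerk_d2(tau) / Tf^2
  for (j in 1:3) {
    s <- s + ct[j] * path_basis(tau, j)
    s1 <- s1 + ct[j] * path_basis_d1(tau, j) / Tf
    s2 <- s2 + ct[j] * path_basis_d2(tau, j) / Tf^2
  }
  lx <- 0; lx1 <- 0; lx2 <- 0
  for (j in 1:3) {
    lx <- lx + cl[j] * path_basis(tau, j)
    lx1 <- lx1 + cl[j] * path_basis_d1(tau, j) / Tf
    lx2 <- lx2 + cl[j] * path_basis_d2(tau, j) / Tf^2
  }
  D <- task$distance
  ee <- rbind(task$start_ee[1] + lx, task$start_ee[2] + D * s)
  eed <- rbind(lx1, D * s1)
  eedd <- rbind(lx2, D * s2)

  q <- matrix(0, 2, n_nodes); qd <- q; qdd <- q
  a <- matrix(0, 6, n_nodes)
  Treq <- matrix(0, 2, n_nodes)
  for (k in seq_len(n_nodes)) {
    qk <- ee_inverse_kinematics(ee[, k], arm)
    J <- ee_jacobian(qk, arm)
    qdk <- solve(J, eed[, k])
    Jd <- ee_jacobian_dot(qk, qdk, arm)
    qddk <- solve(J, eedd[, k] - Jd %*% qdk)
    q[, k] <- qk; qd[, k] <- qdk; qdd[, k] <- qddk
    M <- arm_mass_matrix(qk, arm)
    Cor <- arm_coriolis_rhs(qk, qdk, arm)
    Treq_k <- as.numeric(M %*% qddk) - Cor
    if (task$ff_strength > 0) {
      fff <- divergent_force(ee[, k], task$start_ee[1], task$ff_strength)
      Treq_k <- Treq_k - as.numeric(t(J) %*% fff)
    }
    mg <- reach_muscle_geometry(qk[1], qk[2], qdk[1], qdk[2], gt)
    flv <- fl_active(mg$lnorm, curves) * fv_mult(mg$vnorm, curves)
    fpass <- gt$f_iso * (fp_passive(mg$lnorm, curves) + gt$beta * mg$vnorm)
    Tpass <- c(sum(mg$dm_s * fpass), sum(mg$dm_e * fpass))
    W <- rbind(mg$dm_s * gt$f_iso * flv, mg$dm_e * gt$f_iso * flv)
    a[, k] <- static_activations(W, Treq_k - Tpass)
    Treq[, k] <- Treq_k
  }
  # exact inverse of the activation dynamics: e = a + tau_act * da/dt
  adot <- a
  adot[, 2:(n_nodes - 1)] <- (a[, 3:n_nodes] - a[, 1:(n_nodes - 2)]) /
    (2 * diff(times)[1])
  adot[, 1] <- (a[, 2] - a[, 1]) / diff(times)[1]
  adot[, n_nodes] <- (a[, n_nodes] - a[, n_nodes - 1]) / diff(times)[1]
  e_ff <- a + params$tau * adot

  w <- rep(diff(times)[1], n_nodes); w[c(1, n_nodes)] <- w[1] / 2
  effort <- sum(w * colSums(e_ff^2))
  pen <- sum(w * colSums(pmax(-e_ff, 0)^2 + pmax(e_ff - 1, 0)^2))
  list(times = times, q = q, qd = qd, qdd = qdd, ee = ee, eed = eed,
       a = a, e_ff = e_ff, effort = effort, bound_penalty = pen,
       trapz_w = w)
}

# Stage A: optimize the path coefficients for minimal feedforward effort.
solve_reach_mean <- function(task, params, maxit = 250) {
  npar <- 6L
  obj <- function(theta) {
    tr <- tryCatch(reach_mean_trajectory(theta, task, params),
                   error = function(e) NULL)
    if (is.null(tr)) return(1e6)
    tr$effort + 100 * tr$bound_penalty
  }
  opt <- stats::optim(numeric(npar), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  tr <- reach_mean_trajectory(opt$par, task, params)
  tr$theta <- opt$par
  tr$stageA_convergence <- opt$convergence
  tr
}

# Precompute node-wise linearization data along the frozen mean trajectory.
reach_linearization <- function(tr, task, params) {
  dyn <- reach_model(task, params)
  n <- length(tr$times)
  A <- vector("list", n); H <- vector("list", n); Cm <- vector("list", n)
  for (k in seq_len(n)) {
    xk <- c(tr$q[, k], tr$qd[, k], tr$a[, k])
    ek <- tr$e_ff[, k]
    A[[k]] <- cs_jacobian(function(x) dyn$rhs(0, x, ek, numeric(2)), xk)
    H[[k]] <- cs_jacobian(function(x)
      forward_kinematics(x[1:2], x[3:4], params$arm), xk)
    Minv <- solve(arm_mass_matrix(tr$q[, k], params$arm))
    Cmk <- matrix(0, 10, 2); Cmk[3:4, ] <- Minv
    Cm[[k]] <- Cmk
  }
  list(A = A, H = H, Cm = Cm, dyn = dyn)
}

# Accuracy constraint table for a task: node index, H row (1 = x, 2 = y).
reach_constraint_table <- function(task, times) {
  n <- length(times)
  tab <- switch(task$kind,
    circle = data.frame(node = c(n, n), row = c(1, 2)),
    force_field = data.frame(node = c(n, n), row = c(1, 2)),
    bar = data.frame(node = n, row = 2),
    obstacle = {
      win <- which(times > task$obstacle_after)
      rbind(data.frame(node = c(n, n), row = c(1, 2)),
            data.frame(node = setdiff(win, n), row = 1))
    })
  tab
}

# Stage B: optimize piecewise-linear feedback gains under accuracy
# constraints with exact adjoint gradients.
solve_reach_gains <- function(tr, lin, task, params, coarse_step = 0.1,
                              al_control = list(), P0 = NULL) {
  n <- length(tr$times)
  dt <- diff(tr$times)[1]
  tau <- params$tau
  Sig_s <- diag(params$noise$sensory_psd, 4)        # PSD (into the plant)
  Sig_sd <- Sig_s / dt                              # control-rate variance
  Sig_m <- diag(params$noise$motor_psd, 2)
  if (is.null(P0)) P0 <- diag(1e-8, 10)
  tc <- seq(0, task$duration, by = coarse_step)
  nc <- length(tc)
  Wt <- matrix(0, n, nc)                            # interpolation weights
  for (k in seq_len(n)) {
    t_k <- tr$times[k]
    i <- min(findInterval(t_k, tc, rightmost.closed = TRUE), nc - 1L)
    w <- (t_k - tc[i]) / (tc[i + 1] - tc[i])
    Wt[k, i] <- 1 - w; Wt[k, i + 1] <- w
  }
  ctab <- reach_constraint_table(task, tr$times)
  bnd <- task$accuracy_sd_bound
  kappa <- tr$trapz_w

  mesh_K <- function(z) {
    Kc <- array(z, dim = c(6, 4, nc))
    lapply(seq_len(n), function(k) {
      Kk <- matrix(0, 6, 4)
      for (i in which(Wt[k, ] != 0)) Kk <- Kk + Wt[k, i] * Kc[, , i]
      Kk
    })
  }

  forward <- function(Kl) {
    P <- vector("list", n)
    P[[1]] <- P0
    for (k in seq_len(n - 1L)) {
      Acl <- lin$A[[k]]
      Acl[5:10, ] <- Acl[5:10, ] + (Kl[[k]] %*% lin$H[[k]]) / tau
      Phi <- diag(10) + dt * Acl
      Q <- lin$Cm[[k]] %*% Sig_m %*% t(lin$Cm[[k]])
      KS <- Kl[[k]] %*% Sig_s %*% t(Kl[[k]]) / tau^2
      Q[5:10, 5:10] <- Q[5:10, 5:10] + KS
      P[[k + 1L]] <- Phi %*% P[[k]] %*% t(Phi) + dt * Q
    }
    P
  }

  fb_effort <- function(Kl, P) {
    val <- 0
    for (k in seq_len(n)) {
      S <- lin$H[[k]] %*% P[[k]] %*% t(lin$H[[k]]) + Sig_sd
      val <- val + kappa[k] * sum((Kl[[k]] %*% S) * Kl[[k]])
    }
    val
  }

  cons_vals <- function(P) {
    vapply(seq_len(nrow(ctab)), function(j) {
      k <- ctab$node[j]; r <- ctab$row[j]
      h <- lin$H[[k]][r, , drop = FALSE]
      sd <- sqrt(as.numeric(h %*% P[[k]] %*% t(h)) + 1e-18)
      (sd - bnd) / bnd
    }, numeric(1))
  }

  fn <- function(z) { Kl <- mesh_K(z); fb_effort(Kl, forward(Kl)) }
  ineq <- function(z) cons_vals(forward(mesh_K(z)))

  grad_al <- function(z, lam_eq, lam_in, mu) {
    Kl <- mesh_K(z)
    P <- forward(Kl)
    cc <- cons_vals(P)
    psi1 <- pmax(0, lam_in + mu * cc)               # d psi / d c
    # node-wise direct derivatives D_k = dJ/dP_k
    D <- vector("list", n)
    for (k in seq_len(n)) {
      KH <- Kl[[k]] %*% lin$H[[k]]
      D[[k]] <- kappa[k] * (t(KH) %*% KH)
    }
    for (j in seq_len(nrow(ctab))) {
      if (psi1[j] == 0) next
      k <- ctab$node[j]; r <- ctab$row[j]
      h <- lin$H[[k]][r, , drop = FALSE]
      sd <- sqrt(as.numeric(h %*% P[[k]] %*% t(h)) + 1e-18)
      D[[k]] <- D[[k]] + psi1[j] * (t(h) %*% h) / (2 * sd * bnd)
    }
    gK <- vector("list", n)
    for (k in seq_len(n)) {
      S <- lin$H[[k]] %*% P[[k]] %*% t(lin$H[[k]]) + Sig_sd
      gK[[k]] <- 2 * kappa[k] * Kl[[k]] %*% S
    }
    Lam <- D[[n]]
    for (k in (n - 1L):1L) {
      Acl <- lin$A[[k]]
      Acl[5:10, ] <- Acl[5:10, ] + (Kl[[k]] %*% lin$H[[k]]) / tau
      Phi <- diag(10) + dt * Acl
      PhiP <- Phi %*% P[[k]]
      gK[[k]] <- gK[[k]] +
        (2 * dt / tau) * (Lam %*% PhiP %*% t(lin$H[[k]]))[5:10, , drop = FALSE] +
        (2 * dt / tau^2) * Lam[5:10, 5:10] %*% Kl[[k]] %*% Sig_s
      Lam <- t(Phi) %*% Lam %*% Phi + D[[k]]
    }
    g <- array(0, dim = c(6, 4, nc))
    for (k in seq_len(n))
      for (i in which(Wt[k, ] != 0))
        g[, , i] <- g[, , i] + Wt[k, i] * gK[[k]]
    as.numeric(g)
  }

  ctrl <- utils::modifyList(list(outer_max = 14L, inner_maxit = 300L,
                                 tol_con = 1e-5, mu0 = 10, mu_factor = 8,
                                 factr = 1e2), al_control)
  res <- al_minimize(fn, numeric(6 * 4 * nc), ineq = ineq, gr = grad_al,
                     control = ctrl)
  Kl <- mesh_K(res$par)
  P <- forward(Kl)
  list(K_mesh = Kl, K_coarse = array(res$par, dim = c(6, 4, nc)),
       coarse_times = tc, P = P, fb_effort = fb_effort(Kl, P),
       cons = cons_vals(P), status = res$status,
       max_violation = res$max_violation, z = res$par,
       fns = list(fn = fn, ineq = ineq, grad_al = grad_al))
}

#' Build the finite-horizon reaching stochastic OCP
#'
#' 0.8 s horizon on a 10 ms mesh (81 nodes). Boundary conditions (start at
#' rest at the start point, mean endpoint on target with zero terminal
#' velocity) and the mean/covariance collocation defects are satisfied by
#' construction in the attached reduced transcription; accuracy constraints
#' are SD bounds per task kind; the objective is expected effort with
#' time-varying feedforward excitations and feedback gains.
#'
#' @param task `reach_task`.
#' @param params parameter list from `reach_defaults()`.
#' @return `stochastic_ocp` with an attached task-specific transcription.
#' @export
build_reach_ocp <- function(task = reach_task(), params = reach_defaults()) {
  dyn <- reach_model(task, params)
  ocp <- stochastic_ocp(
    dynamics = dyn,
    cost_integrand = function(x_mean, e_ff, K, P) sum(e_ff^2),
    ny = 4L, horizon = c(0, task$duration), mesh_dt = params$mesh_dt,
    special = "reach")
  attr(ocp, "task") <- task
  attr(ocp, "params") <- params
  attr(ocp, "transcribe") <- function(ocp) {
    n_nodes <- round(task$duration / params$mesh_dt) + 1L
    n_cov <- 10L * 11L / 2L
    structure(list(
      ocp = ocp,
      n_nodes = n_nodes,
      n_defects_eliminated = (n_nodes - 1L) * (10L + n_cov),
      solve_fn = function(nlp, initial_guess, solver_options)
        solve_reach(task, params, solver_options = solver_options)),
      class = "soc_nlp")
  }
  ocp
}

#' Solve a reaching task
#'
#' Runs the two-stage reduced transcription: mean-path/feedforward
#' optimization, then covariance/gain optimization with adjoint gradients
#' under the task's accuracy constraints. An accuracy bound that cannot be
#' met (for instance 0.2 cm on the circle task) is reported through
#' `status = "infeasible"` with the residual constraint violations.
#'
#' @param task `reach_task`.
#' @param params parameter list from `reach_defaults()`.
#' @param solver_options control list for the stage-B augmented Lagrangian.
#' @param stageA_maxit Nelder-Mead iterations for the mean-path stage.
#' @param coarse_step gain-node spacing in seconds (default 0.1).
#' @return `soc_solution`; the policy holds per-node `e_ff` (nodes x 6) and
#'   `K` (6 x 4 x nodes), the trajectory the mean states and covariances at
#'   the mesh nodes. Attributes: `task`, `params`, `model`, `mean_traj`.
#' @export
solve_reach <- function(task = reach_task(), params = reach_defaults(),
                        solver_options = list(), stageA_maxit = 250,
                        coarse_step = 0.1) {
  tr <- solve_reach_mean(task, params, maxit = stageA_maxit)
  lin <- reach_linearization(tr, task, params)
  sg <- solve_reach_gains(tr, lin, task, params, coarse_step = coarse_step,
                          al_control = solver_options)
  n <- length(tr$times)
  ref_fun <- local({
    tt <- tr$times; ee <- tr$ee; eed <- tr$eed
    function(t) c(stats::approx(tt, ee[1, ], t, rule = 2)$y,
                  stats::approx(tt, ee[2, ], t, rule = 2)$y,
                  stats::approx(tt, eed[1, ], t, rule = 2)$y,
                  stats::approx(tt, eed[2, ], t, rule = 2)$y)
  })
  K_arr <- array(0, dim = c(6, 4, n))
  for (k in seq_len(n)) K_arr[, , k] <- sg$K_mesh[[k]]
  pol <- control_policy(e_ff = t(tr$e_ff), K = K_arr,
                        reference = ref_fun, times = tr$times)
  mean_states <- cbind(t(tr$q), t(tr$qd), t(tr$a))
  colnames(mean_states) <- lin$dyn$labels
  traj <- gaussian_trajectory(tr$times, mean_states, sg$P)
  status <- sg$status
  if (sg$max_violation > 0.05) status <- "infeasible"
  sol <- soc_solution(
    policy = pol, trajectory = traj,
    objective_value = tr$effort + sg$fb_effort,
    status = status,
    constraint_residuals = list(accuracy = sg$cons,
                                max_violation = sg$max_violation),
    info = list(theta = tr$theta, ff_effort = tr$effort,
                fb_effort = sg$fb_effort, stageA = tr$stageA_convergence))
  attr(sol, "task") <- task
  attr(sol, "params") <- params
  attr(sol, "model") <- lin$dyn
  attr(sol, "mean_traj") <- tr
  sol
}

#' Time-averaged co-contraction index per antagonist pair
#'
#' CCI(t) = min(a_flex, a_ext)/max(a_flex, a_ext) * (a_flex + a_ext),
#' averaged over time per pair; a sample where both activations are zero
#' contributes zero (limit convention).
#'
#' @param activations n_muscle x n_time matrix with rownames matching the
#'   muscle names, or a `soc_solution` from `solve_reach`.
#' @param pairs named list of antagonist pairs (flexor, extensor).
#' @return named numeric vector of time-averaged CCI per pair.
#' @export
reach_cci <- function(activations, pairs = reach_defaults()$pairs) {
  if (inherits(activations, "soc_solution")) {
    A <- t(activations$trajectory$mean[, 5:10])
    rownames(A) <- reach_muscle_names
    activations <- A
  }
  vapply(pairs, function(pr) {
    af <- activations[pr[1], ]; ax <- activations[pr[2], ]
    mx <- pmax(af, ax)
    mean(ifelse(mx <= 0, 0, (pmin(af, ax) / mx) * (af + ax)))
  }, numeric(1))
}

#' Outcome measures of a reach solution
#'
#' @param solution `soc_solution` from `solve_reach`.
#' @return list: `terminal_sd_cm` (x, y), `cci` per pair, `max_lateral_dev`
#'   of the mean path (m), effort decomposition and status.
#' @export
reach_outcomes <- function(solution) {
  task <- attr(solution, "task")
  params <- attr(solution, "params")
  n <- length(solution$trajectory$times)
  xN <- solution$trajectory$mean[n, ]
  vN <- ee_variance(xN, solution$trajectory$cov[[n]], params)
  tr <- attr(solution, "mean_traj")
  list(terminal_sd_cm = 100 * sqrt(vN[1:2]),
       cci = reach_cci(solution),
       max_lateral_dev = max(abs(tr$ee[1, ] - task$start_ee[1])),
       ff_effort = solution$info$ff_effort,
       fb_effort = solution$info$fb_effort,
       objective = solution$objective_value,
       status = solution$status)
}

#' Endpoint stiffness by simulated force probes
#'
#' Reproduces the experimental protocol in simulation: from the mean state at
#' `probe_time` the closed-loop deterministic dynamics are integrated for the
#' probe interval with and without a constant endpoint force of
#' `probe_magnitude` N along `probe_direction`; stiffness is the applied
#' force change divided by the resulting endpoint displacement along the
#' probe direction at the end of the interval.
#'
#' @param solution `soc_solution` from `solve_reach`.
#' @param probe_times times (s) at which to probe.
#' @param probe_direction unit vector `c(x, y)` (normalized internally).
#' @param probe_magnitude probe force (N), default 3.
#' @param probe_interval interval length (s), default 0.15.
#' @param dt_sim simulation step (default 1 ms).
#' @return data.frame with columns `time`, `stiffness` (N/m; NA when the
#'   displacement is numerically zero -- reported as unmeasurable).
#' @export
endpoint_stiffness <- function(solution, probe_times, probe_direction = c(1, 0),
                               probe_magnitude = 3, probe_interval = 0.15,
                               dt_sim = 1e-3) {
  model <- attr(solution, "model")
  params <- attr(solution, "params")
  dirn <- probe_direction / sqrt(sum(probe_direction^2))
  zero_noise <- noise_spec(rep(0, length(model$noise$psd)),
                           model$noise$labels, model$noise$role)
  x_at <- function(tt) {
    times <- solution$trajectory$times
    k <- which.min(abs(times - tt))
    solution$trajectory$mean[k, ]
  }
  out <- lapply(probe_times, function(tp) {
    x0 <- x_at(tp)
    run <- function(force_on) {
      pert <- if (force_on) {
        function(t, x) as.numeric(t(ee_jacobian(x[1:2], params$arm)) %*%
                                    (probe_magnitude * dirn))
      } else function(t, x) c(0, 0)
      sub_pol <- shift_policy(solution$policy, tp)
      ep <- simulate_episode(sub_pol, model, dt_sim = dt_sim,
                             t_final = probe_interval, seed = 1L, x0 = x0,
                             noise = zero_noise, perturb = pert)
      xe <- ep$states[, ncol(ep$states)]
      forward_kinematics(xe[1:2], xe[3:4], params$arm)[1:2]
    }
    ee1 <- run(TRUE); ee0 <- run(FALSE)
    disp <- sum((ee1 - ee0) * dirn)
    data.frame(time = tp,
               stiffness = if (abs(disp) < 1e-9) NA_real_
                           else probe_magnitude / disp)
  })
  do.call(rbind, out)
}

# time-shifted view of a mesh policy (probe simulations start mid-movement);
# the reference is shifted accordingly and held at its terminal value beyond
# the horizon.
shift_policy <- function(policy, t0) {
  ref <- policy$reference
  control_policy(e_ff = policy$e_ff, K = policy$K,
                 reference = function(t) ref(t + t0),
                 times = policy$times - t0)
}
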