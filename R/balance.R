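# Standing-balance instantiation: inverted pendulum on a stochastically
# perturbed platform, actuated by soleus (SOL) and tibialis anterior (TA),
# with proprioceptive (platform-relative) and vestibular (space-fixed)
# feedback. State ordering: x = (q, qdot, a_SOL, a_TA, q_SS, qdot_SS); the
# segment angle q is measured from vertical, positive = forward lean
# (ankle dorsiflexion); the ankle angle is q_A = q - q_SS.

balance_state_labels <- c("q", "qd", "a_SOL", "a_TA", "q_SS", "qd_SS")

#' Balance perturbation / sensory condition
#'
#' @param perturbation "none", "rotation" or "translation".
#' @param magnitude_index 1..7 selecting the packaged perturbation schedule
#'   entry (1 is the near-zero magnitude).
#' @param sensory "healthy" (proprioceptive + vestibular) or
#'   "vestibular_loss" (vestibular gain columns excluded).
#' @param srs logical: augment the Hill muscles with short-range stiffness.
#' @return object of class `balance_condition`.
#' @export
balance_condition <- function(perturbation = c("none", "rotation", "translation"),
                              magnitude_index = 1L,
                              sensory = c("healthy", "vestibular_loss"),
                              srs = FALSE) {
  perturbation <- match.arg(perturbation)
  sensory <- match.arg(sensory)
  stopifnot(magnitude_index >= 1L, magnitude_index <= 7L)
  structure(list(perturbation = perturbation,
                 magnitude_index = as.integer(magnitude_index),
                 sensory = sensory, srs = isTRUE(srs)),
            class = "balance_condition")
}

# Force along the tendon of one pendulum muscle at ankle angle/velocity,
# activation a (possibly noisy) and optional SRS about the upright fiber
# length. Complex-analytic in all arguments; vectorized elementwise.
balance_muscle_force <- function(qA, qAd, a, mp, geom, curves,
                                 srs = FALSE, ln_mean = NULL, a_base = NULL) {
  g <- mtu_geometry_scalar(qA, geom)
  vmt <- -g$dm * qAd                      # dl/dq = -moment arm
  fib <- rigid_tendon_fiber(g$len, vmt, mp)
  f <- hill_force(a, fib$lnorm, fib$vnorm, mp, curves)
  if (srs) f <- f + srs_force(a_base, fib$lnorm, ln_mean, mp)
  list(force = f * fib$cos_penn, moment_arm = g$dm, lnorm = fib$lnorm)
}

# vector-friendly single-joint geometry (mtu_geometry wraps lists; this keeps
# the hot path free of list allocation)
mtu_geometry_scalar <- function(q, geom) {
  list(len = geom$a * q + geom$b * sin(geom$c * q) + geom$d,
       dm = -(geom$a + geom$b * geom$c * cos(geom$c * q)))
}

#' Balance model dynamics
#'
#' Builds the `stochastic_dynamics` of the perturbed-standing model for a
#' given condition: pendulum equation of motion with gravitational and muscle
#' torques over (m l^2 + I), a fictitious-force term from the translational
#' platform acceleration (lever arm l cos q), first-order activation dynamics,
#' and zero drift for the platform states. Disturbance sources: proprioceptive
#' and vestibular position/velocity noise (sensory), SOL/TA activation noise
#' and the platform translational acceleration (system).
#'
#' @param condition `balance_condition`.
#' @param params parameter list from `balance_defaults()`.
#' @return `stochastic_dynamics` with attribute `aux` (precomputed constants).
#' @export
balance_model <- function(condition = balance_condition(),
                          params = balance_defaults()) {
  pp <- params$pendulum
  denom <- pp$mass * pp$length^2 + pp$inertia
  mgl <- pp$mass * pp$gravity * pp$length
  ml <- pp$mass * pp$length
  tau <- params$tau
  curves <- params$curves
  msol <- params$muscles$SOL; mta <- params$muscles$TA
  gsol <- params$geometry$SOL; gta <- params$geometry$TA
  # upright fiber lengths (SRS reference, self-consistent: mean posture is upright)
  ln0_sol <- rigid_tendon_fiber(gsol$d, 0, msol)$lnorm
  ln0_ta  <- rigid_tendon_fiber(gta$d, 0, mta)$lnorm
  srs <- condition$srs

  trans_psd <- if (condition$perturbation == "translation")
    params$noise$translation_sd[condition$magnitude_index]^2 else 0
  noise <- noise_spec(
    psd = c(params$noise$sensory_psd, params$noise$motor_psd,
            w_trans = trans_psd),
    labels = c("wp_q", "wp_qd", "wv_q", "wv_qd", "w_sol", "w_ta", "w_trans"),
    role = c(rep("sensory", 4), rep("motor", 3)))

  rhs <- function(t, x, e, wm) {
    vec_in <- !is.matrix(x)
    if (vec_in) { x <- matrix(x, ncol = 1); e <- matrix(e, ncol = 1)
                  wm <- matrix(wm, ncol = 1) }
    q <- x[1, ]; qd <- x[2, ]; aS <- x[3, ]; aT <- x[4, ]
    qSS <- x[5, ]; qSSd <- x[6, ]
    qA <- q - qSS; qAd <- qd - qSSd
    fS <- balance_muscle_force(qA, qAd, aS + wm[1, ], msol, gsol, curves,
                               srs, ln0_sol, aS)
    fT <- balance_muscle_force(qA, qAd, aT + wm[2, ], mta, gta, curves,
                               srs, ln0_ta, aT)
    torque <- fS$force * fS$moment_arm + fT$force * fT$moment_arm
    qdd <- (mgl * sin(q) + torque) / denom + (ml * cos(q) / denom) * wm[3, ]
    out <- rbind(qd, qdd,
                 (e[1, ] - aS) / tau, (e[2, ] - aT) / tau,
                 0 * q, 0 * q, deparse.level = 0)
    if (vec_in) out[, 1] else out
  }

  feedback_signal <- function(t, x, ws, ref) {
    if (is.matrix(x))
      rbind(x[1, ] - x[5, ] + ws[1, ], x[2, ] - x[6, ] + ws[2, ],
            x[1, ] + ws[3, ], x[2, ] + ws[4, ])
    else
      c(x[1] - x[5] + ws[1], x[2] - x[6] + ws[2],
        x[1] + ws[3], x[2] + ws[4])
  }

  dyn <- stochastic_dynamics(state_dim = 6L, control_dim = 2L, rhs = rhs,
                             feedback_signal = feedback_signal, noise = noise,
                             labels = balance_state_labels)
  attr(dyn, "aux") <- list(denom = denom, mgl = mgl, ml = ml,
                           ln0 = c(SOL = re_part(ln0_sol), TA = re_part(ln0_ta)),
                           condition = condition, params = params)
  dyn
}

#' Build the stationary balance stochastic OCP
#'
#' Task: maintain mean upright posture (q = qdot = 0, mean state derivatives
#' zero) with constant state covariance (`Pdot = 0`) while minimizing expected
#' effort `e_ff_SOL^2 + e_ff_TA^2 + Var(e_fb_SOL) + Var(e_fb_TA)`. Sway stays
#' within the limits of stability through the chance constraint
#' `|q| <= 10 deg` backed off at `gamma = 2`. Platform states are pinned:
#' rotations impose their Table-valued covariance, translations enter as an
#' acceleration PSD only.
#'
#' @param condition `balance_condition`.
#' @param params parameter list from `balance_defaults()`.
#' @return `stochastic_ocp` (stationary).
#' @export
build_balance_ocp <- function(condition = balance_condition(),
                              params = balance_defaults()) {
  dyn <- balance_model(condition, params)
  sens_cov <- diag(params$noise$sensory_psd / params$mesh_dt, 4)
  H <- cs_jacobian(function(x) dyn$feedback_signal(0, x, numeric(4), NULL),
                   numeric(6))
  K_mask <- matrix(TRUE, 2, 4)
  if (condition$sensory == "vestibular_loss") K_mask[, 3:4] <- FALSE

  pinned_cov <- if (condition$perturbation == "rotation") {
    sd_q <- deg2rad(params$noise$rotation_sd_deg$q[condition$magnitude_index])
    sd_qd <- deg2rad(params$noise$rotation_sd_deg$qd[condition$magnitude_index])
    diag(c(sd_q^2, sd_qd^2), 2)
  } else diag(c(0, 0), 2)

  bnd <- deg2rad(params$sway_bound_deg)
  constraints <- list(
    chance_constraint(function(x) x[1], gamma = params$gamma,
                      direction = "le", bound = bnd),
    chance_constraint(function(x) x[1] + bnd, gamma = params$gamma,
                      direction = "ge"))

  cost <- function(x_mean, e_ff, K, P)
    expected_effort(e_ff, K, P, H, sens_cov)

  # Closed-loop Jacobians exploit model structure: the open-loop state
  # Jacobian is exactly affine in the mean activations (muscle force is
  # affine in activation), the excitation-input matrix B and the sensory /
  # motor disturbance columns are constant at the upright mean, and the
  # feedback path contributes B K H. Agreement with the generic complex-step
  # linearization is asserted in the test suite.
  B <- cs_jacobian(function(e) dyn$rhs(0, numeric(6), e, numeric(3)),
                   numeric(2))
  A_of_a <- local({
    base <- cs_jacobian(function(x) dyn$rhs(0, x, c(0, 0), numeric(3)),
                        numeric(6))
    dS <- cs_jacobian(function(x) dyn$rhs(0, x, c(0, 0), numeric(3)),
                      c(0, 0, 1, 0, 0, 0)) - base
    dT <- cs_jacobian(function(x) dyn$rhs(0, x, c(0, 0), numeric(3)),
                      c(0, 0, 0, 1, 0, 0)) - base
    function(a) base + a[1] * dS + a[2] * dT
  })
  C_motor <- cs_jacobian(function(w) dyn$rhs(0, numeric(6), c(0, 0), w),
                         numeric(3))
  linearizer <- function(x_mean, e_ff, K) {
    A <- A_of_a(x_mean[3:4])
    A[3:4, ] <- A[3:4, ] + (K %*% H) / params$tau
    list(A = A, C = cbind(B %*% K, C_motor))
  }

  mb <- matrix(c(-Inf, Inf), 2, 6)
  mb[, 3:4] <- c(0, 1)

  ocp <- stochastic_ocp(
    dynamics = dyn, cost_integrand = cost, ny = 4L,
    constraints = constraints,
    horizon = "stationary", mesh_dt = params$mesh_dt,
    fixed_mean = stats::setNames(c(0, 0, 0, 0), c("1", "2", "5", "6")),
    mean_bounds = mb,
    pinned_states = 5:6, pinned_cov = pinned_cov,
    K_mask = K_mask, linearizer = linearizer)
  attr(ocp, "H") <- H
  attr(ocp, "sens_cov") <- sens_cov
  attr(ocp, "condition") <- condition
  attr(ocp, "params") <- params
  ocp
}

# Static activation pair satisfying upright torque balance: torque is affine
# in the activations at fixed posture, so a_TA follows from a_SOL by a linear
# solve. Returns c(a_SOL, a_TA).
balance_static_pair <- function(a_sol, dyn) {
  f2 <- function(aS, aT) dyn$rhs(0, c(0, 0, aS, aT, 0, 0),
                                 c(aS, aT), numeric(3))[2]
  c0 <- f2(0, 0); cS <- f2(1, 0) - c0; cT <- f2(0, 1) - c0
  a_ta <- -(c0 + cS * a_sol) / cT
  c(a_sol, max(0, a_ta))
}

# Heuristic stabilizing initial gains: soleus responds to forward lean and
# forward velocity, split across proprioceptive and vestibular channels
# (or proprioceptive only under vestibular loss); scaled up until the
# closed-loop body block is Hurwitz.
balance_initial_gains <- function(ocp, g_q = 4, g_qd = 1) {
  condition <- attr(ocp, "condition")
  w <- if (condition$sensory == "vestibular_loss") c(1, 0) else c(0.75, 0.25)
  K <- rbind(c(w[1] * g_q, w[1] * g_qd, w[2] * g_q, w[2] * g_qd),
             c(0, 0, 0, 0))
  nlp_probe <- function(K) {
    pol <- control_policy(c(0.01, 0.01), K)
    lin <- linearize_closed_loop(ocp$dynamics, pol, numeric(6))
    ev <- eigen(lin$A[1:4, 1:4], only.values = TRUE)$values
    max(Re(ev))
  }
  scale <- 1
  for (i in 1:20) {
    if (nlp_probe(scale * K) < -0.05) break
    scale <- scale * 1.5
  }
  scale * K
}

#' Solve a stationary balance problem
#'
#' Transcribes and solves the balance OCP for one condition. The initial
#' guess uses a small co-contraction pair satisfying static torque balance and
#' heuristic stabilizing gains, or a warm start from a previous solution
#' (`warm`) when sweeping perturbation magnitudes.
#'
#' @param condition `balance_condition`.
#' @param params parameters from `balance_defaults()`.
#' @param warm optional `soc_solution` of a neighboring condition.
#' @param solver_options control list for `al_minimize`.
#' @param reduced use the exact equality elimination (default): upright
#'   torque balance is affine in the activations, so `a_TA` follows from
#'   `a_SOL` by a linear solve and `e_ff = a` enforces activation
#'   stationarity; the remaining problem over `(a_SOL, K)` has only the sway
#'   chance constraints. `reduced = FALSE` solves the full transcription with
#'   explicit stationarity equalities instead (slower; used for
#'   cross-validation).
#' @return `soc_solution` with attributes `condition`, `ocp`.
#' @export
solve_balance <- function(condition = balance_condition(),
                          params = balance_defaults(),
                          warm = NULL, solver_options = list(),
                          reduced = TRUE) {
  ocp <- build_balance_ocp(condition, params)
  nlp <- soc_transcribe(ocp)
  if (!is.null(warm)) {
    z0 <- warm$info$z
  } else {
    a0 <- balance_static_pair(0.01, ocp$dynamics)
    K0 <- balance_initial_gains(ocp)
    z0 <- c(a0, a0, K0[which(ocp$K_mask)])
  }
  if (!reduced) {
    opts <- utils::modifyList(list(outer_max = 12L, inner_maxit = 250L,
                                   tol_con = 1e-8), solver_options)
    sol <- soc_solve(nlp, initial_guess = z0, solver_options = opts)
    attr(sol, "condition") <- condition
    attr(sol, "ocp") <- ocp
    return(sol)
  }
  nk <- length(nlp$kfree)
  to_full <- function(zr) {
    pair <- balance_static_pair(zr[1], ocp$dynamics)
    c(pair, pair, zr[1 + seq_len(nk)])
  }
  zr0 <- c(z0[1], z0[4 + seq_len(nk)])
  opts <- utils::modifyList(list(outer_max = 6L, inner_maxit = 400L,
                                 tol_con = 1e-8, factr = 1e2), solver_options)
  res <- al_minimize(function(zr) nlp$objective(to_full(zr)), zr0,
                     ineq = if (is.null(nlp$ineq)) NULL else
                       function(zr) nlp$ineq(to_full(zr)),
                     lower = c(0, rep(-Inf, nk)),
                     upper = c(0.95, rep(Inf, nk)),
                     control = opts)
  zf <- to_full(res$par)
  s <- nlp$make_PK(zf)
  status <- if (is.null(s$P)) "unstable" else res$status
  pol <- control_policy(s$e_ff, s$K)
  traj <- if (!is.null(s$P))
    gaussian_trajectory(0, matrix(s$x_mean, 1,
                                  dimnames = list(NULL, balance_state_labels)),
                        list(s$P)) else NULL
  sol <- soc_solution(policy = pol, trajectory = traj,
                      objective_value = res$value, status = status,
                      constraint_residuals = list(
                        eq = nlp$eq(zf), ineq = res$ineq,
                        max_violation = max(0, abs(nlp$eq(zf)),
                                            if (length(res$ineq)) res$ineq else -Inf)),
                      info = list(z = zf, z_reduced = res$par, A = s$A, C = s$C))
  attr(sol, "condition") <- condition
  attr(sol, "ocp") <- ocp
  sol
}

#' Outcome measures of a balance solution
#'
#' @param solution converged `soc_solution` from `solve_balance`.
#' @param condition `balance_condition` (defaults to the one attached to the
#'   solution).
#' @return list: `sway_sd_deg` (SD of the pendulum angle), `ankle_sd_deg`,
#'   `prop_weight` = ||K_prop||_F / (||K_prop||_F + ||K_vest||_F), `cci`
#'   (co-contraction index of the mean activations), `fb_effort_fraction`,
#'   `loss_of_balance` (sway RMS > 5 deg), `objective`, `status`.
#' @export
balance_outcomes <- function(solution, condition = attr(solution, "condition")) {
  ocp <- attr(solution, "ocp")
  P <- solution$trajectory$cov[[1]]
  x <- solution$trajectory$mean[1, ]
  K <- solution$policy$K
  e_ff <- solution$policy$e_ff
  sway_sd <- rad2deg(sqrt(max(P[1, 1], 0)))
  ankle_var <- P[1, 1] - 2 * P[1, 5] + P[5, 5]
  kp <- sqrt(sum(K[, 1:2]^2)); kv <- sqrt(sum(K[, 3:4]^2))
  a <- x[3:4]
  cci <- if (max(a) <= 0) 0 else (min(a) / max(a)) * sum(a)
  Y <- attr(ocp, "H") %*% P %*% t(attr(ocp, "H")) + attr(ocp, "sens_cov")
  eff_fb <- sum(diag(K %*% Y %*% t(K)))
  eff_ff <- sum(e_ff^2)
  list(sway_sd_deg = sway_sd,
       ankle_sd_deg = rad2deg(sqrt(max(ankle_var, 0))),
       prop_weight = if (kp + kv == 0) NA_real_ else kp / (kp + kv),
       cci = cci,
       fb_effort_fraction = if (eff_ff + eff_fb == 0) NA_real_
                            else eff_fb / (eff_ff + eff_fb),
       loss_of_balance = sway_sd > 5,
       objective = solution$objective_value,
       status = solution$status)
}

#' Sweep balance conditions with warm starting
#'
#' Solves a list of conditions ordered by increasing perturbation magnitude,
#' warm-starting each solve from the previous solution (homotopy over
#' magnitude), and collects the outcome measures.
#'
#' @param conditions list of `balance_condition`s, ordered by magnitude.
#' @param params parameters from `balance_defaults()`.
#' @param solver_options control list for `al_minimize`.
#' @return data.frame of outcomes, one row per condition, with the solutions
#'   attached as attribute `"solutions"`.
#' @export
sweep_conditions <- function(conditions, params = balance_defaults(),
                             solver_options = list()) {
  sols <- vector("list", length(conditions))
  warm <- NULL
  rows <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    sols[[i]] <- solve_balance(conditions[[i]], params, warm = warm,
                               solver_options = solver_options)
    if (sols[[i]]$status %in% c("converged", "inner_failure"))
      warm <- sols[[i]]
    oc <- balance_outcomes(sols[[i]])
    rows[[i]] <- data.frame(
      perturbation = conditions[[i]]$perturbation,
      magnitude_index = conditions[[i]]$magnitude_index,
      sensory = conditions[[i]]$sensory,
      srs = conditions[[i]]$srs,
      sway_sd_deg = oc$sway_sd_deg, ankle_sd_deg = oc$ankle_sd_deg,
      prop_weight = oc$prop_weight, cci = oc$cci,
      fb_effort_fraction = oc$fb_effort_fraction,
      loss_of_balance = oc$loss_of_balance,
      objective = oc$objective, status = oc$status,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  out
}
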