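# Planar reaching instantiation: two-segment arm (shoulder + elbow hinge
# joints, horizontal plane, no gravity torque) driven by six Hill-type
# rigid-tendon muscles, with time-varying linear feedback of the noisy
# end-effector position/velocity error relative to the nominal (mean)
# end-effector trajectory. State ordering:
# x = (q_s, q_e, qd_s, qd_e, a_BRACH, a_LATTRI, a_ANTDEL, a_POSTDEL,
#      a_BIC, a_LONGTRI).

reach_muscle_names <- c("BRACH", "LATTRI", "ANTDEL", "POSTDEL",
                        "BIC", "LONGTRI")

#' Reaching task definition
#'
#' Point-to-point reach of `distance` m in `duration` s with accuracy imposed
#' as bounds on the standard deviation of the terminal end-effector position:
#' `circle` bounds both coordinates, `bar` (horizontal bar target) only the
#' vertical one, `obstacle` additionally bounds the horizontal SD for
#' `t > obstacle_after` and keeps the mean path on the straight line,
#' `force_field` is the circle task inside a divergent force field of
#' `ff_strength` N/m pushing the hand away from the straight start-target
#' line.
#'
#' @param kind one of "circle", "bar", "obstacle", "force_field".
#' @param duration movement time (s).
#' @param distance reach distance (m).
#' @param accuracy_sd_bound SD bound on the constrained coordinates (m).
#' @param obstacle_after window start for the obstacle constraint (s).
#' @param ff_strength divergent-field strength (N/m).
#' @param start_ee start hand position (m), shoulder at the origin; the
#'   target is `start_ee + (0, distance)`.
#' @return object of class `reach_task`.
#' @export
reach_task <- function(kind = c("circle", "bar", "obstacle", "force_field"),
                       duration = 0.8, distance = 0.25,
                       accuracy_sd_bound = 0.004, obstacle_after = 0.25,
                       ff_strength = 200, start_ee = c(0, 0.35)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, duration = duration, distance = distance,
                 accuracy_sd_bound = accuracy_sd_bound,
                 obstacle_after = obstacle_after,
                 ff_strength = if (kind == "force_field") ff_strength else 0,
                 start_ee = start_ee,
                 target_ee = start_ee + c(0, distance)),
            class = "reach_task")
}

#' Forward kinematics of the two-link arm
#'
#' @param q joint angles `c(q_s, q_e)` (rad; flexion positive), or a 2 x N
#'   matrix.
#' @param q_dot joint velocities, same shape.
#' @param params arm parameter list (`reach_defaults()$arm`).
#' @return vector `c(EE_x, EE_y, EEdot_x, EEdot_y)` (4 x N matrix for matrix
#'   input).
#' @export
forward_kinematics <- function(q, q_dot, params = reach_defaults()$arm) {
  vec_in <- !is.matrix(q)
  if (vec_in) { q <- matrix(q, ncol = 1); q_dot <- matrix(q_dot, ncol = 1) }
  l1 <- params$l1; l2 <- params$l2
  qs <- q[1, ]; qe <- q[2, ]; qsd <- q_dot[1, ]; qed <- q_dot[2, ]
  s1 <- sin(qs); c1 <- cos(qs); s12 <- sin(qs + qe); c12 <- cos(qs + qe)
  x <- l1 * c1 + l2 * c12
  y <- l1 * s1 + l2 * s12
  xd <- -l1 * s1 * qsd - l2 * s12 * (qsd + qed)
  yd <-  l1 * c1 * qsd + l2 * c12 * (qsd + qed)
  out <- rbind(x, y, xd, yd, deparse.level = 0)
  if (vec_in) out[, 1] else out
}

# position Jacobian d(EE_x, EE_y)/d(q_s, q_e)
ee_jacobian <- function(q, params = reach_defaults()$arm) {
  l1 <- params$l1; l2 <- params$l2
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-l1 * s1 - l2 * s12, -l2 * s12,
            l1 * c1 + l2 * c12,  l2 * c12), 2, 2, byrow = TRUE)
}

# time derivative of the position Jacobian
ee_jacobian_dot <- function(q, qd, params = reach_defaults()$arm) {
  l1 <- params$l1; l2 <- params$l2
  w1 <- qd[1]; w12 <- qd[1] + qd[2]
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-l1 * c1 * w1 - l2 * c12 * w12, -l2 * c12 * w12,
           -l1 * s1 * w1 - l2 * s12 * w12, -l2 * s12 * w12), 2, 2,
         byrow = TRUE)
}

# inverse kinematics (elbow-flexed branch, q_e > 0)
ee_inverse_kinematics <- function(ee, params = reach_defaults()$arm) {
  l1 <- params$l1; l2 <- params$l2
  r2 <- ee[1]^2 + ee[2]^2
  ce <- (r2 - l1^2 - l2^2) / (2 * l1 * l2)
  if (any(re_part(ce) >= 1 | re_part(ce) <= -1))
    stop("ee_inverse_kinematics: point outside reachable workspace")
  qe <- acos(ce)
  qs <- atan2(ee[2], ee[1]) - atan2(l2 * sin(qe), l1 + l2 * cos(qe))
  c(qs, qe)
}

#' Two-link arm mass matrix
#' @param q joint angles `c(q_s, q_e)`.
#' @param params arm parameter list.
#' @return symmetric positive-definite 2 x 2 mass matrix.
#' @export
arm_mass_matrix <- function(q, params = reach_defaults()$arm) {
  p <- params
  ce <- cos(q[2])
  m11 <- p$I1 + p$I2 + p$m1 * p$r1^2 +
         p$m2 * (p$l1^2 + p$r2^2 + 2 * p$l1 * p$r2 * ce)
  m12 <- p$I2 + p$m2 * (p$r2^2 + p$l1 * p$r2 * ce)
  m22 <- p$I2 + p$m2 * p$r2^2
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# Coriolis/centrifugal term C(q, qd) on the right-hand side of
# M qdd = C + T + w  (i.e. C = -c(q, qd) of the standard form M qdd + c = T).
arm_coriolis_rhs <- function(q, qd, params = reach_defaults()$arm) {
  h <- params$m2 * params$l1 * params$r2 * sin(q[2])
  c(h * (2 * qd[1] * qd[2] + qd[2]^2), -h * qd[1]^2)
}

#' Divergent force-field force at the end effector
#'
#' Horizontal force proportional to the horizontal deviation of the hand from
#' the straight start-target line, pushing away from the line; zero vertical
#' component.
#'
#' @param ee_position hand position `c(x, y)`.
#' @param line_x horizontal position of the nominal line.
#' @param strength field strength (N/m), >= 0.
#' @return planar force `c(F_x, 0)`.
#' @export
divergent_force <- function(ee_position, line_x, strength) {
  if (re_part(strength) < 0) stop("divergent_force: strength must be >= 0")
  c(strength * (ee_position[1] - line_x), 0 * ee_position[1])
}

# muscle geometry tables flattened to vectors for the vectorized hot path
reach_geom_tables <- function(params) {
  g <- params$geometry
  list(as = vapply(g, `[[`, 0, "as"), bs = vapply(g, `[[`, 0, "bs"),
       ss = vapply(g, `[[`, 0, "ss"), ae = vapply(g, `[[`, 0, "ae"),
       be = vapply(g, `[[`, 0, "be"), se = vapply(g, `[[`, 0, "se"),
       d = vapply(g, `[[`, 0, "d"),
       f_iso = vapply(params$muscles, `[[`, 0, "f_iso_max"),
       beta = vapply(params$muscles, `[[`, 0, "damping_beta"),
       vmax = vapply(params$muscles, `[[`, 0, "v_max_norm"))
}

# Normalized fiber lengths/velocities and moment arms of the six arm muscles
# at scalar joint state (complex-safe). Returns lists of length-6 vectors.
reach_muscle_geometry <- function(qs, qe, qsd, qed, gt) {
  dls <- gt$as + gt$bs * cos(qs)          # d l_norm / d q_s
  dle <- gt$ae + gt$be * cos(qe)
  ln <- gt$d + gt$as * qs + gt$bs * sin(qs) + gt$ae * qe + gt$be * sin(qe)
  vn <- (dls * qsd + dle * qed) / gt$vmax
  list(lnorm = ln, vnorm = vn, dm_s = -gt$ss * dls, dm_e = -gt$se * dle)
}

#' Reaching model dynamics
#'
#' Builds the `stochastic_dynamics` of the planar reach: rigid-body equations
#' of motion with mass matrix and Coriolis terms, muscle torques from the six
#' Hill-type muscles through their moment arms, first-order activation
#' dynamics (tau = 0.15 s), additive joint-torque motor noise, and (for the
#' force-field task) the divergent field mapped to joint torques through the
#' position Jacobian. The feedback signal is the noisy end-effector
#' position/velocity minus the reference trajectory. The right-hand side
#' accepts an optional external joint-torque input `tau_ext` used by the
#' forward simulator for perturbations and stiffness probes.
#'
#' @param task `reach_task`.
#' @param params parameter list from `reach_defaults()`.
#' @return `stochastic_dynamics` with attribute `aux`.
#' @export
reach_model <- function(task = reach_task(), params = reach_defaults()) {
  gt <- reach_geom_tables(params)
  arm <- params$arm
  curves <- params$curves
  tau <- params$tau
  ffk <- task$ff_strength
  line_x <- task$start_ee[1]
  l1 <- arm$l1; l2 <- arm$l2; r2 <- arm$r2; m2 <- arm$m2
  i11c <- arm$I1 + arm$I2 + arm$m1 * arm$r1^2 + m2 * (l1^2 + r2^2)
  i12c <- arm$I2 + m2 * r2^2
  hcoef <- m2 * l1 * r2

  noise <- noise_spec(
    psd = c(params$noise$sensory_psd, params$noise$motor_psd),
    labels = c("w_ee_x", "w_ee_y", "w_ee_xd", "w_ee_yd", "w_s", "w_e"),
    role = c(rep("sensory", 4), rep("motor", 2)))

  rhs <- function(t, x, e, wm, tau_ext = NULL) {
    vec_in <- !is.matrix(x)
    if (vec_in) { x <- matrix(x, ncol = 1); e <- matrix(e, ncol = 1)
                  wm <- matrix(wm, ncol = 1) }
    qs <- x[1, ]; qe <- x[2, ]; qsd <- x[3, ]; qed <- x[4, ]
    a <- x[5:10, , drop = FALSE]
    ce <- cos(qe); se <- sin(qe)
    # muscle forces and torques (vectorized over muscles and columns)
    n <- ncol(x)
    Ts <- 0; Te <- 0
    for (i in 1:6) {
      dls <- gt$as[i] + gt$bs[i] * cos(qs)
      dle <- gt$ae[i] + gt$be[i] * cos(qe)
      ln <- gt$d[i] + gt$as[i] * qs + gt$bs[i] * sin(qs) +
            gt$ae[i] * qe + gt$be[i] * sin(qe)
      vn <- (dls * qsd + dle * qed) / gt$vmax[i]
      f <- gt$f_iso[i] * (a[i, ] * fl_active(ln, curves) * fv_mult(vn, curves) +
                          fp_passive(ln, curves) + gt$beta[i] * vn)
      Ts <- Ts - gt$ss[i] * dls * f
      Te <- Te - gt$se[i] * dle * f
    }
    if (ffk > 0) {
      eex <- l1 * cos(qs) + l2 * cos(qs + qe)
      fx <- ffk * (eex - line_x)
      s1 <- sin(qs); s12 <- sin(qs + qe)
      Ts <- Ts + (-l1 * s1 - l2 * s12) * fx
      Te <- Te + (-l2 * s12) * fx
    }
    T1 <- Ts + wm[1, ] + hcoef * se * (2 * qsd * qed + qed * qed)
    T2 <- Te + wm[2, ] - hcoef * se * qsd * qsd
    if (!is.null(tau_ext)) { T1 <- T1 + tau_ext[1, ]; T2 <- T2 + tau_ext[2, ] }
    m11 <- i11c + 2 * hcoef * ce
    m12 <- i12c + hcoef * ce
    m22 <- i12c
    det <- m11 * m22 - m12 * m12
    qsdd <- (m22 * T1 - m12 * T2) / det
    qedd <- (m11 * T2 - m12 * T1) / det
    out <- rbind(qsd, qed, qsdd, qedd, (e - a) / tau, deparse.level = 0)
    if (vec_in) out[, 1] else out
  }

  feedback_signal <- function(t, x, ws, ref) {
    if (is.matrix(x)) {
      fk <- forward_kinematics(x[1:2, , drop = FALSE],
                               x[3:4, , drop = FALSE], arm)
      fk + ws - ref
    } else {
      forward_kinematics(x[1:2], x[3:4], arm) + ws - ref
    }
  }

  dyn <- stochastic_dynamics(state_dim = 10L, control_dim = 6L, rhs = rhs,
                             feedback_signal = feedback_signal, noise = noise,
                             output_maps = list(
                               ee = function(x) forward_kinematics(x[1:2], x[3:4], arm)),
                             labels = c("q_s", "q_e", "qd_s", "qd_e",
                                        paste0("a_", reach_muscle_names)))
  attr(dyn, "aux") <- list(task = task, params = params, gt = gt)
  dyn
}

#' Linear-propagated end-effector variance
#'
#' Variances of the end-effector position and velocity obtained by projecting
#' the state covariance through the Jacobian of the forward kinematics at the
#' mean state: `diag(J P J')`.
#'
#' @param mean_state length-10 mean state.
#' @param P 10 x 10 state covariance.
#' @param params parameter list from `reach_defaults()`.
#' @return named vector `c(ee_x, ee_y, ee_xd, ee_yd)` of variances.
#' @export
ee_variance <- function(mean_state, P, params = reach_defaults()) {
  J <- cs_jacobian(function(x)
    forward_kinematics(x[1:2], x[3:4], params$arm), mean_state)
  v <- diag(J %*% P %*% t(J))
  names(v) <- c("ee_x", "ee_y", "ee_xd", "ee_yd")
  v
}
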