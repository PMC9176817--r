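#' Hill-type muscle parameters
#'
#' @param f_iso_max maximal isometric force (N), > 0.
#' @param tendon_slack_length tendon slack length (m); rigid-tendon pendulum
#'   model only, NA otherwise.
#' @param optimal_fiber_length optimal fiber length (m); NA when lengths are
#'   parameterized directly in normalized units (arm model).
#' @param pennation_opt pennation angle at optimal fiber length (rad).
#' @param v_max_norm maximal contraction velocity in optimal fiber lengths
#'   per second (default 10).
#' @param damping_beta normalized damping coefficient (default 0.01).
#' @param k_srs short-range-stiffness scaling factor (default 1).
#' @return object of class `muscle_params`.
#' @export
muscle_params <- function(f_iso_max, tendon_slack_length = NA,
                          optimal_fiber_length = NA, pennation_opt = 0,
                          v_max_norm = 10, damping_beta = 0.01, k_srs = 1) {
  stopifnot(f_iso_max > 0, damping_beta >= 0, k_srs >= 0)
  structure(list(f_iso_max = f_iso_max,
                 tendon_slack_length = tendon_slack_length,
                 optimal_fiber_length = optimal_fiber_length,
                 pennation_opt = pennation_opt,
                 v_max_norm = v_max_norm,
                 damping_beta = damping_beta,
                 k_srs = k_srs),
            class = "muscle_params")
}

#' First-order excitation-to-activation dynamics
#'
#' Activation follows excitation with time constant `tau`, lumping sensory and
#' motor delays: `da/dt = (e - a)/tau`.
#'
#' @param excitation,activation current excitation and activation.
#' @param tau time constant in seconds (default 0.15), > 0.
#' @return activation rate (1/s).
#' @export
activation_dynamics <- function(excitation, activation, tau = 0.15) {
  if (re_part(tau) <= 0) stop("activation_dynamics: tau must be positive")
  (excitation - activation) / tau
}

#' Hill-type rigid-tendon muscle force
#'
#' `F = F_iso (a fl(l) fv(l, ldot) + fp(l) + beta ldot)`. Activation is not
#' clipped here: Gaussian noise on the activation may drive it outside [0, 1]
#' and the curve set is defined on the full real line.
#'
#' @param activation activation (possibly noisy, unbounded).
#' @param fiber_length_norm normalized fiber length.
#' @param fiber_velocity_norm normalized fiber velocity.
#' @param params `muscle_params`.
#' @param curves `muscle_curves`.
#' @return muscle force along the fiber (N).
#' @export
hill_force <- function(activation, fiber_length_norm, fiber_velocity_norm,
                       params, curves = muscle_curves()) {
  params$f_iso_max *
    (activation * fl_active(fiber_length_norm, curves) *
       fv_mult(fiber_velocity_norm, curves) +
     fp_passive(fiber_length_norm, curves) +
     params$damping_beta * fiber_velocity_norm)
}

#' Short-range-stiffness force
#'
#' Activation-proportional parallel elastic force resisting deviations of the
#' fiber length from its mean-posture value:
#' `F_SRS = k_srs F_iso a (l - l_mean)/l_opt` (all lengths normalized, so
#' `l_opt = 1`). The spring acts for stretch of any size (no break-away
#' threshold).
#'
#' @param activation baseline activation.
#' @param fiber_length_norm current normalized fiber length.
#' @param fiber_length_mean_norm normalized fiber length at the mean posture.
#' @param params `muscle_params`.
#' @return SRS force (N); odd in the stretch and linear in activation.
#' @export
srs_force <- function(activation, fiber_length_norm, fiber_length_mean_norm,
                      params) {
  params$k_srs * params$f_iso_max * activation *
    (fiber_length_norm - fiber_length_mean_norm)
}

#' Muscle-tendon geometry: length and moment arms from one coefficient set
#'
#' Muscle-tendon length (single joint) is `l(q) = a q + b sin(c q) + d`;
#' for biarticular arm muscles the normalized fiber length is the additive
#' two-joint form `l(qs, qe) = d0 + as qs + (bs/cs) sin(cs qs) + ae qe +
#' (be/ce) sin(ce qe)`. The moment arm about each joint is the negative
#' (scaled) derivative of the length with respect to that angle, so a muscle
#' that shortens when an angle increases has a positive moment arm and
#' produces positive torque; length and moment arm always derive from the
#' same coefficients, which enforces their consistency by construction.
#'
#' @param joint_angles scalar angle (single-joint form) or `c(qs, qe)`.
#' @param coeffs for a single joint: list(a, b, c, d); for the arm muscles:
#'   list(as, bs, cs, ss, ae, be, ce, se, d) with `ss`, `se` the moment-arm
#'   denormalization scales (m); set the *s or *e block to zero for
#'   uniarticular muscles.
#' @return list with `length` and `moment_arms` (one per articulated joint).
#' @export
mtu_geometry <- function(joint_angles, coeffs) {
  if (!is.null(coeffs$a)) {          # single-joint absolute length (m)
    q <- joint_angles[1]
    len <- coeffs$a * q + coeffs$b * sin(coeffs$c * q) + coeffs$d
    dm <- -(coeffs$a + coeffs$b * coeffs$c * cos(coeffs$c * q))
    return(list(length = len, moment_arms = dm))
  }
  if (is.null(coeffs$as)) stop("mtu_geometry: missing geometry coefficients")
  qs <- joint_angles[1]; qe <- joint_angles[2]
  term <- function(a, b, cc, q) {
    if (re_part(cc) == 0) a * q else a * q + (b / cc) * sin(cc * q)
  }
  dterm <- function(a, b, cc, q) {
    if (re_part(cc) == 0) a else a + b * cos(cc * q)
  }
  len <- coeffs$d + term(coeffs$as, coeffs$bs, coeffs$cs, qs) +
                    term(coeffs$ae, coeffs$be, coeffs$ce, qe)
  list(length = len,
       moment_arms = c(-coeffs$ss * dterm(coeffs$as, coeffs$bs, coeffs$cs, qs),
                       -coeffs$se * dterm(coeffs$ae, coeffs$be, coeffs$ce, qe)))
}

# Rigid-tendon fiber state for the pendulum muscles: fiber length from the
# muscle-tendon length with constant muscle height w = l_opt sin(alpha_opt),
# fiber velocity from the muscle-tendon velocity projected on the fiber.
rigid_tendon_fiber <- function(lmt, vmt, params) {
  w <- params$optimal_fiber_length * sin(params$pennation_opt)
  proj <- lmt - params$tendon_slack_length
  lm <- sqrt(proj * proj + w * w)
  vn <- (proj / lm) * vmt / (params$optimal_fiber_length * params$v_max_norm)
  list(lnorm = lm / params$optimal_fiber_length, vnorm = vn,
       cos_penn = proj / lm)
}
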