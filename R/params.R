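# Packaged model parameter registries.
#
# All printed model constants (segment properties, muscle properties, noise
# PSDs, task definitions) live here as named defaults. Geometry coefficients
# are fitted defaults chosen for physiologically plausible moment arms (ankle:
# soleus about -5 cm, tibialis anterior about +4 cm near neutral; arm muscles
# 2-3.5 cm) and can be replaced through the model config. Internal units are
# SI (rad, m, s, N); degree- and millimeter-valued table entries are converted
# here, exactly once.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Default parameter set for the standing-balance model
#'
#' Inverted pendulum (70 kg, 1 m) on a rotatable/translatable platform,
#' actuated by soleus and tibialis anterior. Noise PSDs: proprioceptive
#' 0.1^2 deg^2/Hz (position) and 0.2^2 (deg/s)^2/Hz (velocity), vestibular
#' 0.3^2 and 0.6^2, motor 0.01^2 1/Hz per muscle; platform rotation schedules
#' (random-constant variance, deg) 0.001..4 (position) and 0.001..9.6 (deg/s,
#' velocity) squared; translation acceleration PSDs 0.001^2..0.56^2
#' (m/s^2)^2/Hz. Sway limit: |q| <= 10 deg backed off at gamma = 2.
#'
#' @return nested list of parameters (SI units unless suffixed `_deg`).
#' @export
balance_defaults <- function() {
  sol <- muscle_params(f_iso_max = 5137, tendon_slack_length = 0.2514,
                       optimal_fiber_length = 0.0528, pennation_opt = 0.4364)
  ta  <- muscle_params(f_iso_max = 3000, tendon_slack_length = 0.2228,
                       optimal_fiber_length = 0.1028, pennation_opt = 0.0873)
  geom_sol <- list(a = 0.045, b = 0.005, c = 1,
                   d = 0.2514 + 0.0528 * cos(0.4364))
  geom_ta  <- list(a = -0.036, b = -0.004, c = 1,
                   d = 0.2228 + 0.1028 * cos(0.0873))
  list(
    pendulum = list(mass = 70, length = 1, gravity = 9.81,
                    inertia = 70 * 1^2 / 12),
    tau = 0.15,
    muscles = list(SOL = sol, TA = ta),
    geometry = list(SOL = geom_sol, TA = geom_ta),
    curves = muscle_curves(),
    noise = list(
      sensory_psd = c(p_q  = deg2rad(0.1)^2,  p_qd = deg2rad(0.2)^2,
                      v_q  = deg2rad(0.3)^2,  v_qd = deg2rad(0.6)^2),
      motor_psd = c(m_sol = 0.01^2, m_ta = 0.01^2),
      rotation_sd_deg  = list(q  = c(0.001, 0.125, 0.25, 0.5, 1, 2, 4),
                              qd = c(0.001, 0.3, 0.6, 1.2, 2.4, 4.8, 9.6)),
      translation_sd = c(0.001, 0.0175, 0.035, 0.07, 0.14, 0.28, 0.56)),
    sway_bound_deg = 10, gamma = 2,
    mesh_dt = 0.01)
}

#' Default parameter set for the planar reaching model
#'
#' Two-segment arm (upper arm 1.4 kg / 0.3 m / 0.025 kg m^2, forearm 1.0 kg /
#' 0.33 m / 0.045 kg m^2, COM mid-segment) driven by six Hill-type muscles
#' (brachialis, lateral triceps, anterior/posterior deltoid, biceps, long
#' triceps). Sensory noise on hand position 0.6^2 mm^2/Hz and velocity 4.8^2
#' (mm/s)^2/Hz; motor torque noise 0.05^2 (Nm)^2/Hz per joint. Task: 25 cm
#' reach in 0.8 s, accuracy SD bound 0.4 cm, divergent-field strength 200 N/m.
#'
#' @return nested list of parameters (SI units).
#' @export
reach_defaults <- function() {
  f_iso <- c(BRACH = 572, LATTRI = 445, ANTDEL = 700,
             POSTDEL = 382, BIC = 159, LONGTRI = 318)
  muscles <- lapply(f_iso, function(f)
    muscle_params(f_iso_max = f, v_max_norm = 10, damping_beta = 0.01))
  g2 <- function(ss, as, bs, cs, se, ae, be, ce)
    list(ss = ss, as = as, bs = bs, cs = cs,
         se = se, ae = ae, be = be, ce = ce, d = NA)
  geometry <- list(
    BRACH   = g2(0,   0,     0,    1, 0.1, -0.22, -0.03, 1),
    LATTRI  = g2(0,   0,     0,    1, 0.1,  0.22,  0.03, 1),
    ANTDEL  = g2(0.1, -0.30, -0.03, 1, 0,    0,     0,   1),
    POSTDEL = g2(0.1,  0.30,  0.03, 1, 0,    0,     0,   1),
    BIC     = g2(0.1, -0.26, -0.02, 1, 0.1, -0.22, -0.02, 1),
    LONGTRI = g2(0.1,  0.26,  0.02, 1, 0.1,  0.22,  0.02, 1))
  q_ref <- c(deg2rad(40), deg2rad(80))   # posture where fibers sit at optimum
  for (nm in names(geometry)) {
    g <- geometry[[nm]]; g$d <- 0
    geometry[[nm]]$d <- 1 - re_part(mtu_geometry(q_ref, g)$length)
  }
  list(
    arm = list(m1 = 1.4, l1 = 0.3, I1 = 0.025, r1 = 0.15,
               m2 = 1.0, l2 = 0.33, I2 = 0.045, r2 = 0.165),
    tau = 0.15,
    muscles = muscles,
    geometry = geometry,
    curves = muscle_curves(),
    pairs = list(shoulder = c("ANTDEL", "POSTDEL"),
                 elbow = c("BRACH", "LATTRI"),
                 biarticular = c("BIC", "LONGTRI")),
    noise = list(
      sensory_psd = c(ee_x = 0.6e-3^2, ee_y = 0.6e-3^2,
                      ee_xd = 4.8e-3^2, ee_yd = 4.8e-3^2),
      motor_psd = c(w_s = 0.05^2, w_e = 0.05^2)),
    task = list(duration = 0.8, distance = 0.25, accuracy_sd = 0.004,
                obstacle_after = 0.25, ff_strength = 200, gamma = 2,
                start_ee = c(0, 0.35)),
    mesh_dt = 0.01)
}
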