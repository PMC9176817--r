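# Analytic validation fixtures: self-contained linear problems whose exact
# solutions pin the core covariance/effort/transcription machinery to
# closed-form truths independent of the biomechanical models. The analytic
# reference values are computed by plain closed-form expressions (stationary
# Lyapunov solution, algebraic-Riccati gain), not by the code paths they
# validate.

#' 1D point-mass covariance fixture
#'
#' Position state driven by velocity white noise of PSD 2 (m/s)^2/Hz from
#' zero initial covariance: `A = 0`, `C = 1`. The exact position variance is
#' `P(t) = PSD * t`, independent of the integration step.
#'
#' @param psd velocity-noise PSD (default 2 (m/s)^2/Hz).
#' @return object of class `linear_fixture` with matrices `A`, `C`, `psd`,
#'   `P0` and the closed-form `analytic_P(t)`.
#' @export
point_mass_fixture <- function(psd = 2) {
  structure(list(A = matrix(0, 1, 1), C = matrix(1, 1, 1),
                 psd = matrix(psd, 1, 1), P0 = matrix(0, 1, 1),
                 analytic_P = function(t) psd * t),
            class = "linear_fixture")
}

#' Stationary scalar LQ fixture
#'
#' Unstable scalar plant `xdot = a x + b e + w` (motor noise PSD `sigma^2`),
#' perfect state feedback `y = x - ref`, stationary mean held at `x_target`,
#' and quadratic cost rate `q (x - x_target)^2-ish + r E[e^2]` expressed
#' through the state covariance: `q P + r (e_ff^2 + k^2 P)`. The stationary
#' optimal feedback gain coincides with the continuous-time LQR gain, which
#' the fixture provides from the scalar algebraic Riccati equation:
#' `k* = -(a + sqrt(a^2 + q b^2 / r)) / b`; the stationary covariance is
#' `P* = sigma^2 / (-2 (a + b k*))` and the feedforward follows from mean
#' stationarity `a x_target + b e_ff = 0`.
#'
#' @param a,b plant parameters (`a > 0`: unstable; |a| in [0.5, 2] for
#'   conditioning).
#' @param q,r state and effort weights.
#' @param sigma motor noise PSD^(1/2).
#' @param x_target stationary mean target.
#' @return `linear_fixture` with the `stochastic_ocp` (`$ocp`) and analytic
#'   references (`$k_opt`, `$P_opt`, `$e_ff_opt`, `$objective_opt`).
#' @export
lq_stationary_fixture <- function(a = 0.8, b = 1.2, q = 1, r = 0.5,
                                  sigma = 0.3, x_target = 0.5) {
  noise <- noise_spec(psd = c(sens = 0, mot = sigma^2),
                      labels = c("w_s", "w_m"),
                      role = c("sensory", "motor"))
  rhs <- function(t, x, e, wm) a * x[1] + b * e[1] + wm[1]
  fb <- function(t, x, ws, ref) x[1] + ws[1] - ref
  dyn <- stochastic_dynamics(1L, 1L, rhs = rhs, feedback_signal = fb,
                             noise = noise, labels = "x")
  cost <- function(x_mean, e_ff, K, P) {
    e_mean <- e_ff + K[1, 1] * (x_mean[1] - x_target)  # = e_ff at optimum
    q * P[1, 1] + r * (sum(e_mean^2) + sum((K %*% P %*% t(K))))
  }
  ocp <- stochastic_ocp(dyn, cost, ny = 1L,
                        horizon = "stationary",
                        e_ff_bounds = c(-10, 10),
                        extra_eq = function(x_mean, e_ff, K) x_mean[1] - x_target,
                        reference = x_target)
  # independent closed-form references (scalar ARE)
  k_opt <- -(a + sqrt(a^2 + q * b^2 / r)) / b
  P_opt <- sigma^2 / (-2 * (a + b * k_opt))
  e_ff_opt <- -a * x_target / b
  structure(list(ocp = ocp, a = a, b = b, q = q, r = r, sigma = sigma,
                 x_target = x_target,
                 k_opt = k_opt, P_opt = P_opt, e_ff_opt = e_ff_opt,
                 objective_opt = q * P_opt + r * (e_ff_opt^2 + k_opt^2 * P_opt)),
            class = "linear_fixture")
}
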