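#' Stochastic dynamics container
#'
#' Describes a controlled stochastic system `xdot = f(t, x, e, w_m)` with a
#' feedback signal `y_fb(t, x, w_s, ref)` that is affine in the sensory noise
#' `w_s`. The right-hand side evaluated at zero disturbance must be smooth in
#' state and excitation; all bundled models satisfy this with complex-analytic
#' primitives so closed-loop Jacobians can be taken by complex step.
#'
#' @param state_dim,control_dim integers.
#' @param rhs `function(t, x, e, w_m)` returning the state derivative.
#' @param feedback_signal `function(t, x, w_s, ref)` returning the feedback
#'   vector.
#' @param noise `noise_spec` describing all disturbance sources; the `w_s`
#'   argument receives the "sensory" sources, `w_m` the "motor" sources, in
#'   label order.
#' @param output_maps optional named list of output functions of the state
#'   (e.g. end-effector kinematics) used by constraints.
#' @param labels optional state labels.
#' @return object of class `stochastic_dynamics`.
#' @export
stochastic_dynamics <- function(state_dim, control_dim, rhs, feedback_signal,
                                noise, output_maps = list(), labels = NULL) {
  stopifnot(is.function(rhs), is.function(feedback_signal),
            inherits(noise, "noise_spec"))
  structure(list(state_dim = as.integer(state_dim),
                 control_dim = as.integer(control_dim),
                 noise_dim = length(noise$psd),
                 rhs = rhs, feedback_signal = feedback_signal,
                 noise = noise, output_maps = output_maps, labels = labels),
            class = "stochastic_dynamics")
}

#' Control policy: feedforward excitations plus linear feedback gains
#'
#' Total excitation is `e = e_ff + K y_fb`. For stationary problems `e_ff`
#' is a vector and `K` a matrix; for finite-horizon problems they are given
#' per mesh node (`e_ff`: nodes x m matrix, `K`: m x n_y x nodes array) and
#' interpolated piecewise-linearly in between.
#'
#' @param e_ff feedforward excitation (vector, or nodes x m matrix).
#' @param K feedback gain matrix (m x n_y), or m x n_y x nodes array.
#' @param reference reference for the feedback error: a function of time (or
#'   `NULL` when the feedback signal needs none).
#' @param times mesh times for time-varying policies.
#' @return object of class `control_policy`.
#' @export
control_policy <- function(e_ff, K, reference = NULL, times = NULL) {
  structure(list(e_ff = e_ff, K = K, reference = reference, times = times),
            class = "control_policy")
}

# Evaluate (e_ff, K, ref) of a policy at time t with linear interpolation.
policy_at <- function(policy, t) {
  if (is.null(policy$times)) {
    ref <- if (is.function(policy$reference)) policy$reference(t) else policy$reference
    return(list(e_ff = policy$e_ff, K = policy$K, ref = ref))
  }
  tt <- policy$times
  t <- min(max(t, tt[1L]), tt[length(tt)])
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  i <- min(i, length(tt) - 1L)
  w <- (t - tt[i]) / (tt[i + 1L] - tt[i])
  e_ff <- (1 - w) * policy$e_ff[i, ] + w * policy$e_ff[i + 1L, ]
  K <- (1 - w) * policy$K[, , i] + w * policy$K[, , i + 1L]
  ref <- if (is.function(policy$reference)) policy$reference(t) else policy$reference
  list(e_ff = e_ff, K = matrix(K, nrow = nrow(policy$K)), ref = ref)
}

# Closed-loop rhs with policy substituted; w is the full disturbance vector
# ordered as in dynamics$noise (sensory then motor subvectors by role mask).
closed_loop_rhs <- function(dynamics, policy) {
  is_s <- dynamics$noise$role == "sensory"
  is_m <- dynamics$noise$role == "motor"
  function(t, x, w) {
    p <- policy_at(policy, t)
    y <- dynamics$feedback_signal(t, x, w[is_s], p$ref)
    e <- p$e_ff + as.vector(p$K %*% y)
    dynamics$rhs(t, x, e, w[is_m])
  }
}

#' Linearize the closed-loop stochastic dynamics
#'
#' Substitutes the control policy into the dynamics (so the excitation depends
#' on the state through the feedback law), sets disturbances to zero, and
#' returns the Jacobians of the closed-loop right-hand side with respect to
#' the state (`A`, including the `K dy_fb/dx` path) and to the full
#' disturbance vector (`C`), both evaluated at the mean state. Derivatives are
#' exact (complex step).
#'
#' @param dynamics `stochastic_dynamics`.
#' @param policy `control_policy`.
#' @param mean_state state vector at which to linearize.
#' @param time evaluation time (default 0).
#' @return list with matrices `A` (n x n) and `C` (n x noise_dim, pinned
#'   sources excluded).
#' @export
linearize_closed_loop <- function(dynamics, policy, mean_state, time = 0) {
  f <- closed_loop_rhs(dynamics, policy)
  n_w <- dynamics$noise_dim
  not_pinned <- dynamics$noise$role != "pinned"
  if (length(mean_state) != dynamics$state_dim)
    stop("linearize_closed_loop: state dimension mismatch")
  A <- cs_jacobian(function(x) f(time, x, numeric(n_w)), mean_state)
  Cfull <- cs_jacobian(function(w) {
    wc <- if (is.complex(w)) as.complex(numeric(n_w)) else numeric(n_w)
    wc[not_pinned] <- w
    f(time, mean_state, wc)
  }, numeric(sum(not_pinned)))
  list(A = A, C = Cfull)
}

#' Expected squared-excitation effort of a Gaussian closed loop
#'
#' The expected value of `||e||^2` with `e = e_ff + K (H x~ + w_s)` under the
#' Gaussian state approximation: since the feedback term is zero-mean and
#' uncorrelated with the deterministic feedforward,
#' `E||e||^2 = ||e_ff||^2 + trace(K (H P H' + Sigma_s) K')`.
#'
#' @param e_ff feedforward excitation vector.
#' @param K feedback gain matrix (m x n_y).
#' @param P state covariance.
#' @param feedback_jacobian `H = dy_fb/dx` at the mean state (n_y x n).
#' @param sensory_noise_cov covariance of the additive sensory noise entering
#'   the feedback signal (the PSD discretized at the control interval).
#' @return scalar expected effort.
#' @export
expected_effort <- function(e_ff, K, P, feedback_jacobian, sensory_noise_cov) {
  K <- as.matrix(K)
  H <- as.matrix(feedback_jacobian)
  S <- as.matrix(sensory_noise_cov)
  if (ncol(K) != nrow(H) || ncol(H) != nrow(as.matrix(P)) ||
      any(dim(S) != ncol(K)))
    stop("expected_effort: shape mismatch")
  Y <- H %*% P %*% t(H) + S
  sum(e_ff^2) + sum(diag(K %*% Y %*% t(K)))
}

#' Chance constraint specification
#'
#' A scalar constraint `g(x_mean, u) >= 0` (or `<= bound`) backed off by
#' `gamma` standard deviations of the Gaussian-propagated output:
#' `g(mean) - gamma * sqrt(grad_g P grad_g') >= 0`. `gamma = 2` gives nominal
#' 95% satisfaction of a two-sided bound, `gamma = 3` gives 99.7%.
#'
#' @param g `function(x_mean)` scalar output.
#' @param gamma back-off multiplier >= 0.
#' @param direction `"ge"` for `g >= 0`, `"le"` for `g <= bound`.
#' @param bound upper bound for `direction = "le"` (default 0).
#' @param active_window optional `c(t_min, t_max)` over which the constraint
#'   applies on finite horizons.
#' @return object of class `chance_constraint`.
#' @export
chance_constraint <- function(g, gamma, direction = c("ge", "le"), bound = 0,
                              active_window = NULL) {
  stopifnot(is.function(g), gamma >= 0)
  direction <- match.arg(direction)
  structure(list(g = g, gamma = gamma, direction = direction, bound = bound,
                 active_window = active_window),
            class = "chance_constraint")
}

#' Evaluate the deterministic back-off value of a chance constraint
#'
#' Returns `g(mean) - gamma * sqrt(grad P grad' + eps)` for lower-bound
#' constraints and `bound - g(mean) - gamma * sqrt(...)` for upper bounds, so
#' feasibility is `value >= 0` in both cases. The variance argument is floored
#' at a small positive `eps` to keep the square root differentiable as P -> 0.
#'
#' @param constraint `chance_constraint`.
#' @param mean_state mean state vector.
#' @param P state covariance.
#' @param eps smoothing floor inside the sqrt (default 1e-12).
#' @return scalar back-off constraint value (feasible when >= 0).
#' @export
chance_constraint_value <- function(constraint, mean_state, P, eps = 1e-12) {
  g0 <- constraint$g(mean_state)
  grad <- cs_jacobian(function(x) constraint$g(x), re_part(mean_state))
  v <- as.numeric(grad %*% P %*% t(grad))
  if (re_part(v) < -1e-8) stop("chance_constraint_value: negative variance")
  backoff <- constraint$gamma * sqrt(v + eps)
  if (constraint$direction == "ge") g0 - backoff
  else constraint$bound - g0 - backoff
}

#' Gaussian state trajectory
#'
#' Mean state trajectory and symmetric covariance trajectory at mesh nodes.
#' @param times mesh times.
#' @param mean nodes x n matrix of mean states.
#' @param cov list of n x n covariance matrices, one per node.
#' @return object of class `gaussian_trajectory`.
#' @export
gaussian_trajectory <- function(times, mean, cov) {
  mean <- as.matrix(mean)
  stopifnot(length(times) == nrow(mean), length(cov) == nrow(mean))
  for (P in cov)
    if (symmetry_defect(P) > 1e-8)
      stop("gaussian_trajectory: covariance not symmetric")
  structure(list(times = times, mean = mean, cov = cov),
            class = "gaussian_trajectory")
}

# Solution container returned by soc_solve and the model-level drivers.
soc_solution <- function(policy, trajectory, objective_value, status,
                         constraint_residuals = NULL, info = list()) {
  structure(list(policy = policy, trajectory = trajectory,
                 objective_value = objective_value, status = status,
                 constraint_residuals = constraint_residuals, info = info),
            class = "soc_solution")
}

#' @export
print.soc_solution <- function(x, ...) {
  cat("<soc_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}
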