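test_that("closed-loop linearization recovers analytic Jacobians", {
  # 1D point mass: position driven by velocity disturbance, no feedback
  ns <- noise_spec(c(0, 2), c("ws", "wv"), c("sensory", "motor"))
  dyn <- stochastic_dynamics(1L, 1L,
                             rhs = function(t, x, e, wm) wm[1],
                             feedback_signal = function(t, x, ws, ref) 0 * x[1],
                             noise = ns)
  lin <- linearize_closed_loop(dyn, control_policy(0, matrix(0, 1, 1)), 0)
  expect_equal(lin$A, matrix(0, 1, 1))
  expect_equal(lin$C, matrix(c(0, 1), 1, 2))

  # linear system xdot = a x + b (e_ff + k (x + w_s)) + w_m
  a <- -0.7; b <- 1.4; k <- 0.6
  ns2 <- noise_spec(c(0.1, 0.2), c("ws", "wm"), c("sensory", "motor"))
  dyn2 <- stochastic_dynamics(1L, 1L,
                              rhs = function(t, x, e, wm) a * x[1] + b * e[1] + wm[1],
                              feedback_signal = function(t, x, ws, ref) x[1] + ws[1],
                              noise = ns2)
  lin2 <- linearize_closed_loop(dyn2, control_policy(0, matrix(k, 1, 1)), 0)
  expect_equal(lin2$A[1, 1], a + b * k, tolerance = 1e-12)
  expect_equal(lin2$C, matrix(c(b * k, 1), 1, 2), tolerance = 1e-12)
  expect_error(linearize_closed_loop(dyn2, control_policy(0, matrix(k)), c(0, 0)),
               "dimension")
})

test_that("balance closed-loop Jacobians match a finite-difference oracle", {
  dyn <- balance_model(balance_condition(srs = TRUE))
  K <- matrix(c(2, 0.7, 0.5, 0.2, -1, -0.3, -0.2, -0.1), 2, 4, byrow = TRUE)
  pol <- control_policy(c(0.05, 0.1), K)
  x0 <- c(0.02, -0.01, 0.05, 0.1, 0.005, 0.01)
  lin <- linearize_closed_loop(dyn, pol, x0)
  f <- closed_loop_rhs(dyn, pol)
  A_fd <- fd_jacobian(function(x) f(0, x, numeric(7)), x0)
  C_fd <- fd_jacobian(function(w) f(0, x0, w), numeric(7))
  expect_equal(lin$A, A_fd, tolerance = 1e-6)
  expect_equal(lin$C, C_fd, tolerance = 1e-6)
})

test_that("stationary transcription reduces to a single-node algebraic problem", {
  ocp <- build_balance_ocp(balance_condition())
  nlp <- soc_transcribe(ocp)
  expect_equal(nlp$n_nodes, 1L)
  expect_equal(nlp$n_defects_eliminated, 6L * 7L / 2L)
  # symmetric covariance by construction at a stabilizing point
  a0 <- socmove:::balance_static_pair(0.02, ocp$dynamics)
  K0 <- socmove:::balance_initial_gains(ocp)
  z0 <- c(a0, a0, K0[which(ocp$K_mask)])
  s <- nlp$make_PK(z0)
  expect_lt(max(abs(s$P - t(s$P))), 1e-10)
  expect_gt(min(eigen(s$P, symmetric = TRUE)$values), -1e-8)
})

test_that("finite-horizon reach transcription has the expected mesh arithmetic", {
  nlp <- soc_transcribe(build_reach_ocp(reach_task("circle")))
  expect_equal(nlp$n_nodes, 81L)
  expect_equal(nlp$n_defects_eliminated, 80L * (10L + 55L))
})

test_that("the SOC pipeline recovers the Riccati gain on the LQ fixture", {
  fx <- lq_stationary_fixture()
  nlp <- soc_transcribe(fx$ocp)
  sol <- soc_solve(nlp, initial_guess = c(0, 0, -2),
                   solver_options = list(outer_max = 15L))
  expect_equal(sol$status, "converged")
  u <- nlp$unpack(sol$info$z)
  expect_lt(abs(u$K[1, 1] - fx$k_opt), 1e-4)
  s <- nlp$make_PK(sol$info$z)
  expect_lt(abs(s$P[1, 1] - fx$P_opt), 1e-6)
  expect_equal(sol$objective_value, fx$objective_opt, tolerance = 1e-6)
})

test_that("zero noise reduces the SOC solution to the deterministic problem", {
  fx <- lq_stationary_fixture(sigma = 0)
  nlp <- soc_transcribe(fx$ocp)
  sol <- soc_solve(nlp, initial_guess = c(0, 0, -2),
                   solver_options = list(outer_max = 15L))
  s <- nlp$make_PK(sol$info$z)
  expect_lt(abs(s$P[1, 1]), 1e-12)
  # deterministic optimum: e_ff from mean stationarity, zero variance cost
  det_obj <- fx$r * fx$e_ff_opt^2
  expect_equal(sol$objective_value, det_obj, tolerance = 1e-6)
})
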