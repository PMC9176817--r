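test_that("balance dynamics match an independent re-implementation", {
  p <- balance_defaults()
  dyn <- balance_model(balance_condition(), p)
  # independent oracle: plain transcription of the pendulum + muscle algebra
  oracle <- function(x, e, wm) {
    pp <- p$pendulum
    den <- pp$mass * pp$length^2 + pp$inertia
    qA <- x[1] - x[5]; qAd <- x[2] - x[6]
    musc <- function(mp, g, a) {
      lmt <- g$a * qA + g$b * sin(g$c * qA) + g$d
      dm <- -(g$a + g$b * g$c * cos(g$c * qA))
      vmt <- -dm * qAd
      w <- mp$optimal_fiber_length * sin(mp$pennation_opt)
      proj <- lmt - mp$tendon_slack_length
      lm <- sqrt(proj^2 + w^2)
      ln <- lm / mp$optimal_fiber_length
      vn <- (proj / lm) * vmt / (mp$optimal_fiber_length * mp$v_max_norm)
      f <- mp$f_iso_max * (a * fl_active(ln) * fv_mult(vn) +
                           fp_passive(ln) + mp$damping_beta * vn)
      f * (proj / lm) * dm
    }
    tq <- musc(p$muscles$SOL, p$geometry$SOL, x[3] + wm[1]) +
          musc(p$muscles$TA, p$geometry$TA, x[4] + wm[2])
    c(x[2],
      (pp$mass * pp$gravity * pp$length * sin(x[1]) + tq) / den +
        pp$mass * pp$length * cos(x[1]) / den * wm[3],
      (e[1] - x[3]) / p$tau, (e[2] - x[4]) / p$tau, 0, 0)
  }
  set.seed(8)
  for (i in 1:5) {
    x <- c(rnorm(2, sd = 0.1), runif(2), rnorm(2, sd = 0.05))
    e <- runif(2); wm <- rnorm(3, sd = 0.01)
    expect_equal(dyn$rhs(0, x, e, wm), oracle(x, e, wm), tolerance = 1e-12)
  }
})

test_that("upright rest is an equilibrium and gravity dominates when leaning", {
  dyn <- balance_model(balance_condition())
  f0 <- dyn$rhs(0, numeric(6), c(0, 0), numeric(3))
  expect_lt(max(abs(f0)), 1e-12)
  # static pair keeps torque balance at co-contraction
  pair <- socmove:::balance_static_pair(0.1, dyn)
  fp <- dyn$rhs(0, c(0, 0, pair, 0, 0), pair, numeric(3))
  expect_lt(max(abs(fp)), 1e-10)
  # gravitational acceleration term at q = 0.1 rad (muscle torques oppose)
  p <- balance_defaults()$pendulum
  grav <- p$mass * p$gravity * p$length * sin(0.1) /
          (p$mass * p$length^2 + p$inertia)
  qdd <- dyn$rhs(0, c(0.1, 0, 0, 0, 0, 0), c(0, 0), numeric(3))[2]
  expect_gt(qdd, 0.8 * grav)
  expect_lt(qdd, grav)
})

test_that("sensory channels separate platform-relative and space-fixed cues", {
  dyn <- balance_model(balance_condition())
  y0 <- dyn$feedback_signal(0, numeric(6), numeric(4), NULL)
  expect_equal(y0, rep(0, 4))
  # platform rotation only: proprioception reads -delta, vestibular zero
  delta <- 0.05
  y <- dyn$feedback_signal(0, c(0, 0, 0, 0, delta, 0), numeric(4), NULL)
  expect_equal(y, c(-delta, 0, 0, 0))
  # translations leave the platform angle states at zero: identical cues
  x <- c(0.02, -0.03, 0, 0, 0, 0)
  y <- dyn$feedback_signal(0, x, numeric(4), NULL)
  expect_equal(y[1:2], y[3:4])
})

test_that("the stationary solution satisfies its optimality conditions", {
  sol <- get_balance_healthy()
  expect_equal(sol$status, "converged")
  # mean stationarity at the solution
  expect_lt(max(abs(sol$constraint_residuals$eq)), 1e-7)
  # Lyapunov residual of the stationary covariance
  P <- sol$trajectory$cov[[1]]
  A <- sol$info$A; C <- sol$info$C
  Sig <- diag(c(balance_defaults()$noise$sensory_psd,
                balance_defaults()$noise$motor_psd, 0))
  res <- A %*% P + P %*% t(A) + C %*% Sig %*% t(C)
  expect_lt(max(abs(res)), 1e-7)
  expect_lt(max(abs(P - t(P))), 1e-8)
  expect_gt(min(eigen(P, symmetric = TRUE)$values), -1e-8)
  oc <- balance_outcomes(sol)
  expect_gt(oc$sway_sd_deg, 0.1)
  expect_lt(oc$sway_sd_deg, 2)
  expect_true(oc$prop_weight > 0.5 && oc$prop_weight <= 1)
})

test_that("vestibular loss forces full proprioceptive weighting", {
  sol <- get_balance_vl()
  expect_equal(sol$status, "converged")
  K <- sol$policy$K
  expect_true(all(K[, 3:4] == 0))
  expect_equal(balance_outcomes(sol)$prop_weight, 1)
})

test_that("sway grows monotonically over the translation magnitude sweep", {
  sw <- get_translation_sweep()
  expect_true(all(sw$status %in% c("converged", "max_iterations")))
  expect_true(all(diff(sw$sway_sd_deg) > -1e-6))
  # the sway chance constraint caps the SD at bound / gamma
  p <- balance_defaults()
  expect_lt(max(sw$sway_sd_deg), p$sway_bound_deg / p$gamma + 0.1)
})

test_that("rotations drive sensory reweighting away from proprioception", {
  sw <- sweep_conditions(lapply(c(1, 3, 5, 7), function(i)
    balance_condition("rotation", i)))
  expect_true(all(diff(sw$sway_sd_deg) > -1e-6))
  # increased reliance on vestibular feedback at higher rotation magnitudes
  expect_true(all(diff(sw$prop_weight) < 1e-6))
  expect_lt(sw$prop_weight[4], sw$prop_weight[1] - 0.1)
  # vestibular loss: sway keeps growing with magnitude, proprioception stays at 1
  swv <- sweep_conditions(lapply(c(1, 4), function(i)
    balance_condition("rotation", i, sensory = "vestibular_loss")))
  expect_true(all(swv$prop_weight == 1))
  expect_gt(swv$sway_sd_deg[2], swv$sway_sd_deg[1])
})

test_that("short-range stiffness enables co-contraction at large translations", {
  sw <- get_translation_sweep()
  warm <- attr(sw, "solutions")[[6]]
  sol_srs <- solve_balance(balance_condition("translation", 7, srs = TRUE),
                           warm = warm)
  sol_plain <- attr(sw, "solutions")[[7]]
  cci_srs <- balance_outcomes(sol_srs)$cci
  cci_plain <- balance_outcomes(sol_plain)$cci
  expect_gte(cci_srs, cci_plain)
})

test_that("forward simulation confirms the Lyapunov-predicted sway", {
  sol <- get_balance_healthy()
  model <- balance_model(balance_condition())
  pred_sd <- sqrt(sol$trajectory$cov[[1]][1, 1])
  m2 <- vapply(1:6, function(i) {
    ep <- simulate_episode(sol$policy, model, dt_sim = 1e-3, t_final = 25,
                           seed = 100 + i, x0 = numeric(6))
    q <- ep$states[1, ep$times > 5]
    mean(q^2)
  }, numeric(1))
  emp_sd <- sqrt(mean(m2))
  expect_lt(abs(emp_sd - pred_sd) / pred_sd, 0.15)
})

test_that("the structured balance linearizer agrees with the generic path", {
  ocp <- build_balance_ocp(balance_condition(srs = TRUE))
  u <- list(x_mean = c(0, 0, 0.07, 0.12, 0, 0), e_ff = c(0.07, 0.12),
            K = matrix(rnorm(8), 2, 4))
  fast <- ocp$linearizer(u$x_mean, u$e_ff, u$K)
  gen <- linearize_closed_loop(ocp$dynamics,
                               control_policy(u$e_ff, u$K), u$x_mean)
  expect_equal(fast$A, gen$A, tolerance = 1e-10)
  expect_equal(fast$C, gen$C, tolerance = 1e-10)
})
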