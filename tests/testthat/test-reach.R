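test_that("forward kinematics and Jacobian are consistent", {
  arm <- reach_defaults()$arm
  # fully extended along x
  fk <- forward_kinematics(c(0, 0), c(0, 0), arm)
  expect_equal(fk[1], 0.63)
  expect_equal(fk[2:4], rep(0, 3))
  # zero joint velocities -> zero hand velocity
  fk2 <- forward_kinematics(c(0.7, 1.1), c(0, 0), arm)
  expect_equal(fk2[3:4], c(0, 0))
  # analytic velocity map vs finite differences of the position map
  set.seed(3)
  for (i in 1:5) {
    q <- c(runif(1, 0, 1.5), runif(1, 0.3, 2))
    J_fd <- fd_jacobian(function(qq)
      forward_kinematics(qq, c(0, 0), arm)[1:2], q)
    J <- socmove:::ee_jacobian(q, arm)
    expect_equal(J, J_fd, tolerance = 1e-8)
    # inverse kinematics round trip
    ee <- forward_kinematics(q, c(0, 0), arm)[1:2]
    expect_equal(socmove:::ee_inverse_kinematics(ee, arm), q,
                 tolerance = 1e-10)
  }
})

test_that("mass matrix is symmetric positive definite across postures", {
  arm <- reach_defaults()$arm
  for (qe in seq(0.1, 2.4, by = 0.3)) {
    M <- arm_mass_matrix(c(0.5, qe), arm)
    expect_equal(M[1, 2], M[2, 1])
    expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  }
})

test_that("passive skeleton conserves kinetic energy", {
  p <- reach_defaults()
  for (nm in names(p$muscles)) p$muscles[[nm]]$f_iso_max <- 1e-9
  dyn <- reach_model(reach_task("circle"), p)
  x <- c(0.5, 1.2, 0.8, -0.5, rep(0, 6))
  ke <- function(x) {
    M <- arm_mass_matrix(x[1:2], p$arm)
    0.5 * as.numeric(t(x[3:4]) %*% M %*% x[3:4])
  }
  ke0 <- ke(x)
  dt <- 1e-5
  for (k in 1:20000) x <- x + dt * dyn$rhs(0, x, numeric(6), numeric(2))
  expect_equal(ke(x), ke0, tolerance = 1e-3)
})

test_that("end-effector variance matches a Gaussian sampling oracle", {
  p <- reach_defaults()
  x0 <- c(0.6, 1.3, 0.2, -0.4, rep(0.05, 6))
  expect_equal(unname(ee_variance(x0, diag(0, 10), p)), rep(0, 4))
  # spread small enough for the linear propagation to be the dominant term
  set.seed(12)
  L <- matrix(rnorm(100, sd = 0.01), 10, 10)
  P <- crossprod(L)
  pred <- ee_variance(x0, P, p)
  n <- 1e4
  xs <- x0 + t(chol(P)) %*% matrix(rnorm(10 * n), 10, n)
  ees <- apply(xs, 2, function(x)
    forward_kinematics(x[1:2], x[3:4], p$arm))
  emp <- apply(ees, 1, var)
  se <- sqrt(2 / (n - 1)) * emp
  # linearization bias is small at these scales; allow 3 SE + 5% of the value
  expect_true(all(abs(emp - pred) < 3 * se + 0.05 * pred))
})

test_that("end-effector feedback is a referenced noisy error signal", {
  p <- reach_defaults()
  dyn <- reach_model(reach_task("circle"), p)
  x0 <- c(0.5, 1.4, 0.1, -0.2, rep(0, 6))
  ref <- forward_kinematics(x0[1:2], x0[3:4], p$arm)
  expect_equal(dyn$feedback_signal(0, x0, numeric(4), ref), rep(0, 4))
  w <- c(0.01, -0.02, 0.3, 0.1)
  expect_equal(dyn$feedback_signal(0, x0, w, ref), w)
  H <- cs_jacobian(function(x) dyn$feedback_signal(0, x, numeric(4), ref), x0)
  H_fd <- fd_jacobian(function(x) dyn$feedback_signal(0, x, numeric(4), ref), x0)
  expect_equal(H, H_fd, tolerance = 1e-6)
})

test_that("divergent force field is linear, odd, and vanishes on the line", {
  expect_equal(divergent_force(c(0.3, 1), line_x = 0.3, strength = 200),
               c(0, 0))
  expect_equal(divergent_force(c(0.31, 0.5), 0.3, 200), c(2, 0))
  expect_equal(divergent_force(c(0.29, 0.5), 0.3, 200), c(-2, 0))
  expect_error(divergent_force(c(0, 0), 0, -5), ">= 0")
})

test_that("static activation distribution solves the torque constraint at minimum norm", {
  set.seed(21)
  gt <- socmove:::reach_geom_tables(reach_defaults())
  for (i in 1:5) {
    mg <- socmove:::reach_muscle_geometry(runif(1, 0.3, 1.2),
                                          runif(1, 0.5, 2), 0, 0, gt)
    W <- rbind(mg$dm_s * gt$f_iso, mg$dm_e * gt$f_iso)
    b <- rnorm(2, sd = 2)
    a <- socmove:::static_activations(W, b)
    expect_true(all(a >= 0))
    expect_equal(as.numeric(W %*% a), b, tolerance = 1e-8)
    # KKT: on the active (positive) set, a is in the row space of W
    pos <- a > 1e-9
    if (sum(pos) >= 2) {
      Wp <- W[, pos, drop = FALSE]
      proj <- t(Wp) %*% solve(Wp %*% t(Wp), Wp %*% a[pos])
      expect_equal(as.numeric(proj), a[pos], tolerance = 1e-6)
    }
  }
})

test_that("stage-B adjoint gradient matches finite differences", {
  sol <- get_reach("circle")
  tr <- attr(sol, "mean_traj")
  task <- attr(sol, "task"); p <- attr(sol, "params")
  lin <- socmove:::reach_linearization(tr, task, p)
  sg <- socmove:::solve_reach_gains(tr, lin, task, p,
                                    al_control = list(outer_max = 0L))
  set.seed(33)
  z <- rnorm(length(sg$z), sd = 1)
  lam <- runif(length(sg$cons), 0, 2); mu <- 7
  alf <- function(zz) {
    v <- sg$fns$fn(zz); cc <- sg$fns$ineq(zz)
    act <- (lam + mu * cc) > 0
    v + sum(ifelse(act, lam * cc + 0.5 * mu * cc^2, -lam^2 / (2 * mu)))
  }
  g <- sg$fns$grad_al(z, numeric(0), lam, mu)
  idx <- sample(length(z), 8)
  for (j in idx) {
    h <- 1e-6
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    g_fd <- (alf(zp) - alf(zm)) / (2 * h)
    expect_equal(g[j], g_fd, tolerance = 1e-4)
  }
})

test_that("reach CCI follows its defining formula", {
  A <- matrix(0.1, 6, 81, dimnames = list(socmove:::reach_muscle_names, NULL))
  cci <- reach_cci(A)
  expect_equal(unname(cci), rep(0.2, 3))
  A["LATTRI", ] <- 0
  expect_equal(unname(reach_cci(A)["elbow"]), 0)
  A[] <- 0
  expect_equal(unname(reach_cci(A)), rep(0, 3))
})

test_that("circle task pushes the endpoint variance to the accuracy bound", {
  sol <- get_reach("circle")
  expect_equal(sol$status, "converged")
  oc <- reach_outcomes(sol)
  # at least one terminal accuracy constraint active (within 5% of 0.4 cm)
  expect_true(any(abs(oc$terminal_sd_cm - 0.4) < 0.05 * 0.4))
  expect_true(all(oc$terminal_sd_cm <= 0.4 * 1.05))
  # symmetry/PSD of propagated covariances
  for (P in sol$trajectory$cov[c(1, 41, 81)]) {
    expect_lt(max(abs(P - t(P))), 1e-8)
    expect_gt(min(eigen(P, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("minimum intervention leaves bar-task horizontal errors uncorrected", {
  sol <- get_reach("bar")
  expect_equal(sol$status, "converged")
  oc <- reach_outcomes(sol)
  expect_gt(oc$terminal_sd_cm[1], oc$terminal_sd_cm[2])
  expect_lte(oc$terminal_sd_cm[2], 0.4 * 1.05)
})

test_that("the divergent field straightens the mean reach path", {
  dev_circle <- reach_outcomes(get_reach("circle"))$max_lateral_dev
  dev_field <- reach_outcomes(get_reach("force_field"))$max_lateral_dev
  expect_lt(dev_field, dev_circle)
})

test_that("an 0.2 cm accuracy bound is reported infeasible", {
  sol <- solve_reach(reach_task("circle", accuracy_sd_bound = 0.002),
                     solver_options = list(outer_max = 6L))
  expect_equal(sol$status, "infeasible")
  expect_gt(sol$constraint_residuals$max_violation, 0.01)
})

test_that("force-field control raises horizontal but not reach-direction stiffness", {
  solc <- get_reach("circle")
  solf <- get_reach("force_field")
  ts <- c(0.2, 0.4)
  kx_c <- endpoint_stiffness(solc, ts, c(1, 0))$stiffness
  kx_f <- endpoint_stiffness(solf, ts, c(1, 0))$stiffness
  ky_c <- endpoint_stiffness(solc, ts, c(0, 1))$stiffness
  ky_f <- endpoint_stiffness(solf, ts, c(0, 1))$stiffness
  expect_true(all(kx_f > kx_c))
  expect_true(all(abs(ky_f - ky_c) / pmax(ky_f, ky_c) < 0.2))
})
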