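test_that("activation dynamics is a first-order lag", {
  expect_equal(activation_dynamics(0.4, 0.4), 0)
  expect_equal(activation_dynamics(1, 0, tau = 0.15), 1 / 0.15,
               tolerance = 1e-12)
  expect_error(activation_dynamics(1, 0, tau = 0), "positive")
  # step response reaches 1 - exp(-1) = 63.2% at t = tau
  tau <- 0.15; dt <- 1e-5; a <- 0
  for (k in seq_len(round(tau / dt))) a <- a + dt * activation_dynamics(1, a, tau)
  expect_equal(a, 1 - exp(-1), tolerance = 1e-3)
})

test_that("characteristic curves are normalized at the operating point", {
  expect_equal(fl_active(1), 1, tolerance = 0.02)
  expect_equal(fv_mult(0), 1, tolerance = 0.01)
  expect_equal(fp_passive(1), 0)
  # passive curve non-negative and increasing above optimal length
  l <- seq(1, 1.6, by = 0.05)
  fp <- fp_passive(l)
  expect_true(all(fp >= 0))
  expect_true(all(diff(fp) > 0))
})

test_that("Hill force matches isometric arithmetic", {
  sol_p <- balance_defaults()$muscles$SOL
  # passive-free rest: zero activation at optimal length, zero velocity
  expect_equal(hill_force(0, 1, 0, sol_p), 0)
  # full activation at optimal length ~ F_iso (curve normalization)
  expect_equal(hill_force(1, 1, 0, sol_p) / sol_p$f_iso_max, 1,
               tolerance = 0.01)
  # soleus at half activation: ~ 0.5 * 5137 N
  expect_equal(hill_force(0.5, 1, 0, sol_p), 2568.5, tolerance = 0.01 * 2568.5)
})

test_that("force is non-negative over the working range of the models", {
  # near-optimal lengths and sub-maximal velocities, where the small
  # negative passive tail below optimal length and the damping term cannot
  # dominate the active contribution
  sol_p <- balance_defaults()$muscles$SOL
  grid <- expand.grid(a = c(0.1, 0.3, 0.6, 1), l = seq(0.85, 1.2, by = 0.05),
                      v = seq(-0.5, 0.5, by = 0.25))
  f <- mapply(function(a, l, v) hill_force(a, l, v, sol_p),
              grid$a, grid$l, grid$v)
  expect_true(all(f >= 0))
})

test_that("short-range stiffness is odd in stretch and linear in activation", {
  mp <- balance_defaults()$muscles$SOL
  expect_equal(srs_force(0.5, 1.02, 1.02, mp), 0)
  expect_equal(srs_force(0, 1.1, 1.0, mp), 0)
  # k = 1, F_iso = 5137, a = 0.1, normalized stretch 0.01 -> 5.137 N
  expect_equal(srs_force(0.1, 1.01, 1.00, mp), 5.137, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:10) {
    s <- runif(1, -0.05, 0.05); a <- runif(1)
    expect_equal(srs_force(a, 1 + s, 1, mp), -srs_force(a, 1 - s, 1, mp))
    expect_equal(srs_force(2 * a, 1 + s, 1, mp),
                 2 * srs_force(a, 1 + s, 1, mp))
  }
})

test_that("moment arms are consistent with the length parameterization", {
  # degenerate sinusoid: length linear, moment arm constant
  g0 <- list(a = 0.03, b = 0, c = 1, d = 0.25)
  out <- mtu_geometry(0.37, g0)
  expect_equal(out$length, 0.03 * 0.37 + 0.25)
  expect_equal(out$moment_arms, -0.03)
  # single-joint balance muscles: finite difference of length vs moment arm
  for (g in balance_defaults()$geometry) {
    for (q in seq(-0.4, 0.4, by = 0.1)) {
      dl <- fd_jacobian(function(qq) mtu_geometry(qq, g)$length, q)[1, 1]
      expect_equal(mtu_geometry(q, g)$moment_arms, -dl, tolerance = 1e-8)
    }
  }
  # two-joint arm muscles: both moment arms vs scaled length derivative
  geo <- reach_defaults()$geometry
  for (nm in names(geo)) {
    g <- geo[[nm]]
    for (i in 1:4) {
      q <- c(runif(1, 0.2, 1.4), runif(1, 0.5, 2.0))
      dl <- fd_jacobian(function(qq) mtu_geometry(qq, g)$length, q)
      dm <- mtu_geometry(q, g)$moment_arms
      expect_equal(dm[1], -g$ss * dl[1, 1], tolerance = 1e-8)
      expect_equal(dm[2], -g$se * dl[1, 2], tolerance = 1e-8)
    }
  }
})

test_that("biarticular shoulder moment arm is independent of the elbow angle", {
  g <- reach_defaults()$geometry$BIC
  dm1 <- mtu_geometry(c(0.7, 0.5), g)$moment_arms[1]
  dm2 <- mtu_geometry(c(0.7, 2.0), g)$moment_arms[1]
  expect_equal(dm1, dm2)
  expect_error(mtu_geometry(c(0.7, 0.5), list(foo = 1)), "coefficients")
})
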