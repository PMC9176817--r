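test_that("point-mass covariance reproduces the discretization worked example", {
  fx <- point_mass_fixture()
  # one 1 s step
  expect_equal(propagate_covariance(fx$P0, fx$A, fx$C, fx$psd, 1, 1)[1, 1], 2)
  # 0.1 s steps: P(0.1) = 0.2, P(0.2) = 0.4, P(1) = 2
  Ps <- propagate_covariance(fx$P0, fx$A, fx$C, fx$psd, 0.1, 10, keep = TRUE)
  expect_equal(Ps[[2]][1, 1], 0.2)
  expect_equal(Ps[[3]][1, 1], 0.4)
  expect_equal(Ps[[11]][1, 1], 2)
  # zero elapsed time
  expect_equal(propagate_covariance(fx$P0, fx$A, fx$C, fx$psd, 0.1, 0)[1, 1], 0)
})

test_that("lyapunov_rhs matches its definition and rejects asymmetric input", {
  expect_equal(lyapunov_rhs(matrix(0), matrix(5), matrix(1), matrix(0)),
               matrix(0))
  # stable scalar stationary solution P = sigma^2 / (2 a)
  a <- 1.3; s2 <- 0.7
  P <- s2 / (2 * a)
  expect_equal(lyapunov_rhs(matrix(-a), matrix(P), matrix(1), matrix(s2)),
               matrix(0))
  A <- matrix(rnorm(9), 3, 3)
  Pbad <- matrix(rnorm(9), 3, 3)
  expect_error(lyapunov_rhs(A, Pbad, diag(3), diag(3)), "symmetric")
  # result symmetric by construction for random symmetric input
  Ps <- crossprod(matrix(rnorm(9), 3, 3))
  out <- lyapunov_rhs(A, Ps, diag(3), diag(c(1, 2, 3)))
  expect_lt(max(abs(out - t(out))), 1e-12)
})

test_that("algebraic stationary solution agrees with long-horizon propagation", {
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(rnorm(9), 3, 3); A <- A - (max(Re(eigen(A)$values)) + 1) * diag(3)
    C <- matrix(rnorm(6), 3, 2)
    Sig <- diag(c(0.5, 1.2))
    Pstat <- lyapunov_stationary(A, C %*% Sig %*% t(C))
    Pprop <- propagate_covariance(diag(0, 3), A, C, Sig, dt = 1e-3,
                                  n_steps = 12000)
    expect_lt(max(abs(Pstat - Pprop)), 1e-3 * max(abs(Pstat)) + 1e-8)
    expect_gt(min(eigen(Pstat, symmetric = TRUE)$values), -1e-8)
  }
  expect_error(lyapunov_stationary(matrix(0.1), matrix(1)), "Hurwitz")
})

test_that("Lyapunov covariance matches a brute-force Euler-Maruyama ensemble", {
  a <- -1.1; psd <- 0.8; Tf <- 1; n <- 1e4
  x <- scalar_em_ensemble(a, psd, x0 = 0, t_final = Tf, dt = 0.01,
                          n = n, seed = 99)
  P_pred <- propagate_covariance(matrix(0), matrix(a), matrix(1),
                                 matrix(psd), dt = 0.01,
                                 n_steps = 100)[1, 1]
  v <- var(x)
  se <- sqrt(2 / (n - 1)) * v
  expect_lt(abs(v - P_pred), 3 * se)
})
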