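# Independent numerical oracles used by the tests. These deliberately avoid
# the package's own differentiation and propagation code paths.

# central finite-difference Jacobian
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

# brute-force Euler-Maruyama ensemble for a scalar linear SDE
# dx = a x dt + sigma dW ; returns terminal values of n episodes
scalar_em_ensemble <- function(a, sigma_psd, x0, t_final, dt, n, seed) {
  set.seed(seed)
  n_steps <- round(t_final / dt)
  x <- rep(x0, n)
  sd_step <- sqrt(sigma_psd / dt)
  for (k in seq_len(n_steps)) {
    w <- rnorm(n, sd = sd_step)
    x <- x + dt * (a * x + w)
  }
  x
}
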