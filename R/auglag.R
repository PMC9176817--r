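# Augmented-Lagrangian solver with BFGS inner iterations.
#
# Minimizes f(x) subject to h(x) = 0, c(x) <= 0 and box bounds. The classic
# augmented Lagrangian is used for both equality and inequality constraints
# (Rockafellar form for inequalities). Inner minimizations use L-BFGS-B with
# central finite-difference gradients unless an analytic gradient is supplied.
# This is the workhorse behind soc_solve for reduced-space transcriptions,
# where objective and constraint evaluations are cheap (small dense linear
# algebra) and the decision vector is low-dimensional.

fd_grad <- function(f, x, h = 1e-6) {
  n <- length(x)
  g <- numeric(n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    g[j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  g
}

#' Augmented-Lagrangian minimization
#'
#' @param fn objective `function(x)` returning a finite scalar.
#' @param x0 start vector.
#' @param eq optional `function(x)` returning the equality residual vector.
#' @param ineq optional `function(x)` returning constraint values with the
#'   convention `ineq(x) <= 0` feasible.
#' @param lower,upper box bounds (scalars or vectors).
#' @param gr optional analytic gradient of the augmented Lagrangian factory:
#'   `function(x, lam_eq, lam_in, mu)`; default central finite differences.
#' @param control list: `outer_max` (default 25), `mu0` (10), `mu_factor` (5),
#'   `tol_con` (1e-8), `inner_maxit` (200), `factr` (1e3); `log_file` appends
#'   a per-outer-iteration summary (objective, max violation, penalty weight)
#'   and the final residuals to the given path.
#' @return list with `par`, `value` (objective), `eq`, `ineq`, `status`,
#'   `outer_iters`, `max_violation`.
#' @export
al_minimize <- function(fn, x0, eq = NULL, ineq = NULL,
                        lower = -Inf, upper = Inf, gr = NULL,
                        control = list()) {
  ctrl <- utils::modifyList(list(outer_max = 25L, mu0 = 10, mu_factor = 5,
                                 tol_con = 1e-8, inner_maxit = 200L,
                                 factr = 1e3, log_file = NULL), control)
  logline <- function(...) if (!is.null(ctrl$log_file))
    cat(sprintf(...), "\n", file = ctrl$log_file, append = TRUE)
  n_eq <- if (is.null(eq)) 0L else length(eq(x0))
  n_in <- if (is.null(ineq)) 0L else length(ineq(x0))
  lam_eq <- numeric(n_eq)
  lam_in <- numeric(n_in)
  mu <- ctrl$mu0
  x <- x0
  viol_prev <- Inf
  status <- "max_iterations"
  value <- fn(x)

  al_fun <- function(x, lam_eq, lam_in, mu) {
    v <- fn(x)
    if (n_eq > 0L) {
      h <- eq(x)
      v <- v + sum(lam_eq * h) + 0.5 * mu * sum(h * h)
    }
    if (n_in > 0L) {
      cc <- ineq(x)
      act <- (lam_in + mu * cc) > 0
      v <- v + sum(ifelse(act, lam_in * cc + 0.5 * mu * cc * cc,
                          -lam_in^2 / (2 * mu)))
    }
    v
  }

  for (outer in seq_len(ctrl$outer_max)) {
    L <- function(z) al_fun(z, lam_eq, lam_in, mu)
    gfun <- if (is.null(gr)) function(z) fd_grad(L, z)
            else function(z) gr(z, lam_eq, lam_in, mu)
    opt <- stats::optim(x, L, gr = gfun, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctrl$inner_maxit,
                                       factr = ctrl$factr))
    x <- opt$par
    h <- if (n_eq > 0L) eq(x) else numeric(0)
    cc <- if (n_in > 0L) ineq(x) else numeric(0)
    viol <- max(0, abs(h), cc)
    logline("outer %2d  f = %.8g  viol = %.3g  mu = %.3g  inner = %s",
            outer, fn(x), viol, mu, opt$convergence)
    if (n_eq > 0L) lam_eq <- lam_eq + mu * h
    if (n_in > 0L) lam_in <- pmax(0, lam_in + mu * cc)
    if (viol < ctrl$tol_con) {
      status <- if (opt$convergence %in% c(0L, 1L)) "converged" else "inner_failure"
      value <- fn(x)
      if (opt$convergence == 0L || outer > 2L) break
    }
    if (viol > 0.25 * viol_prev) mu <- mu * ctrl$mu_factor
    viol_prev <- viol
    value <- fn(x)
  }
  logline("final: status = %s  f = %.8g  max_violation = %.3g", status,
          value, if (n_eq + n_in > 0L) viol_prev else 0)
  list(par = x, value = value,
       eq = if (n_eq > 0L) eq(x) else numeric(0),
       ineq = if (n_in > 0L) ineq(x) else numeric(0),
       status = status, outer_iters = outer,
       max_violation = if (n_eq + n_in > 0L)
         max(0, abs(if (n_eq > 0L) eq(x) else 0),
             if (n_in > 0L) ineq(x) else -Inf) else 0)
}
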