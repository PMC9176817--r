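# Monte-Carlo forward simulation (Euler-Maruyama) of a solved policy under
# the full nonlinear stochastic dynamics, plus ensemble-derived measures.

#' Simulate one stochastic episode of a closed-loop policy
#'
#' Euler-Maruyama integration of the nonlinear closed-loop dynamics with
#' fresh Gaussian draws per step and per source, each source discretized as
#' `sd = sqrt(PSD / dt_sim)`. Policy gains and feedforward excitations are
#' interpolated piecewise-linearly between mesh nodes. Reproducible given
#' `seed` (bitwise).
#'
#' @param policy `control_policy`.
#' @param model `stochastic_dynamics`.
#' @param dt_sim simulation step (s), at most the policy mesh interval.
#' @param t_final episode duration (s).
#' @param seed integer seed.
#' @param x0 initial state.
#' @param noise `noise_spec` (defaults to the model's).
#' @param perturb optional `function(t, x)` returning an external joint
#'   torque passed to the dynamics (`tau_ext`), for perturbed reaching and
#'   stiffness probes.
#' @param clip_excitation clip total excitations at zero before they enter
#'   the dynamics (off by default: matches the approximation the optimizer
#'   saw, where the stochastic feedback component is unbounded).
#' @param divergence_bound flag the episode as failed when the state norm
#'   exceeds this bound (default 1e3).
#' @return list with `times`, `states` (n_state x n_steps+1), `excitations`
#'   (n_control x n_steps), `failed`, `seed`.
#' @export
simulate_episode <- function(policy, model, dt_sim = 1e-3, t_final,
                             seed, x0, noise = model$noise, perturb = NULL,
                             clip_excitation = FALSE,
                             divergence_bound = 1e3) {
  set.seed(seed)
  n_steps <- round(t_final / dt_sim)
  is_s <- noise$role == "sensory"; is_m <- noise$role == "motor"
  sd_s <- sqrt(discretize_noise(noise$psd[is_s], dt_sim))
  sd_m <- sqrt(discretize_noise(noise$psd[is_m], dt_sim))
  ns <- sum(is_s); nm <- sum(is_m)
  X <- matrix(0, model$state_dim, n_steps + 1L)
  E <- matrix(0, model$control_dim, n_steps)
  X[, 1] <- x0
  failed <- FALSE
  takes_ext <- "tau_ext" %in% names(formals(model$rhs))
  x <- x0
  for (k in seq_len(n_steps)) {
    t_k <- (k - 1L) * dt_sim
    p <- policy_at(policy, t_k)
    ws <- stats::rnorm(ns, sd = sd_s)
    wm <- stats::rnorm(nm, sd = sd_m)
    y <- model$feedback_signal(t_k, x, ws, p$ref)
    e <- as.numeric(p$e_ff + p$K %*% y)
    if (clip_excitation) e <- pmax(e, 0)
    xdot <- if (takes_ext && !is.null(perturb))
      model$rhs(t_k, x, e, wm, tau_ext = matrix(perturb(t_k, x), ncol = 1))
    else model$rhs(t_k, x, e, wm)
    x <- x + dt_sim * xdot
    X[, k + 1L] <- x
    E[, k] <- e
    if (!all(is.finite(x)) || sqrt(sum(x^2)) > divergence_bound) {
      failed <- TRUE
      break
    }
  }
  list(times = seq(0, t_final, by = dt_sim), states = X, excitations = E,
       failed = failed, seed = seed)
}

#' Simulate an ensemble of episodes
#'
#' Runs `n_episodes` episodes with seeds `seed + 0:(n_episodes-1)` (distinct
#' by construction) under the same policy, model and perturbation schedule.
#'
#' @inheritParams simulate_episode
#' @param n_episodes number of episodes.
#' @param seed base seed; episode i uses `seed + i - 1`.
#' @param x0_fn optional `function(episode_seed)` generating the initial
#'   state (used for random-constant platform states); defaults to `x0`.
#' @return object of class `episode_ensemble`.
#' @export
simulate_ensemble <- function(policy, model, n_episodes, seed, dt_sim = 1e-3,
                              t_final, x0 = NULL, x0_fn = NULL,
                              noise = model$noise, perturb = NULL,
                              clip_excitation = FALSE) {
  eps <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    si <- seed + i - 1L
    xi <- if (!is.null(x0_fn)) x0_fn(si) else x0
    eps[[i]] <- simulate_episode(policy, model, dt_sim = dt_sim,
                                 t_final = t_final, seed = si, x0 = xi,
                                 noise = noise, perturb = perturb,
                                 clip_excitation = clip_excitation)
  }
  structure(list(episodes = eps, n_episodes = n_episodes, dt_sim = dt_sim,
                 seed = seed, perturbed = !is.null(perturb)),
            class = "episode_ensemble")
}

#' 95% confidence ellipse of planar points
#'
#' Ellipse of the empirical 2 x 2 covariance at the chi-square(2) quantile of
#' the requested coverage.
#'
#' @param points n x 2 matrix.
#' @param coverage coverage probability (default 0.95).
#' @return list with `center`, `semi_axes` (decreasing), `orientation` (rad,
#'   major axis), `cov`; `NULL` when fewer than 3 points are supplied.
#' @export
confidence_ellipse <- function(points, coverage = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) return(NULL)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  ed <- eigen(S, symmetric = TRUE)
  r <- sqrt(stats::qchisq(coverage, df = 2) * pmax(ed$values, 0))
  list(center = ctr, semi_axes = r,
       orientation = atan2(ed$vectors[2, 1], ed$vectors[1, 1]),
       cov = S)
}

#' Membership test for a confidence ellipse
#' @param ellipse result of `confidence_ellipse`.
#' @param points n x 2 matrix.
#' @return logical vector: point inside (or on) the ellipse.
#' @export
ellipse_contains <- function(ellipse, points) {
  points <- as.matrix(points)
  d <- sweep(points, 2, ellipse$center)
  Sinv <- solve(ellipse$cov)
  md2 <- rowSums((d %*% Sinv) * d)
  md2 <= stats::qchisq(0.95, df = 2)
}

#' Ensemble-derived outcome measures
#'
#' Terminal end-effector 95% confidence ellipse, corrective muscle
#' activations (each episode's activation time series minus the mean
#' unperturbed activations), and co-contraction statistics.
#'
#' @param ensemble `episode_ensemble` of a reaching policy.
#' @param model the `stochastic_dynamics` the ensemble was simulated with.
#' @param unperturbed_mean optional n_muscle x n_times matrix of mean
#'   activations during unperturbed reaching (required for corrective
#'   activations).
#' @param pairs antagonist pairing as in `reach_defaults()$pairs`.
#' @param activation_rows state rows holding activations (default 5:10).
#' @return list with `ellipse`, `terminal_ee` (n x 2), `terminal_sd`,
#'   `corrective` (list mean, sd) or NULL, `cci` (per-episode per-pair
#'   time-averaged CCI matrix) and `cci_mean`.
#' @export
ensemble_measures <- function(ensemble, model, unperturbed_mean = NULL,
                              pairs = reach_defaults()$pairs,
                              activation_rows = 5:10) {
  ok <- !vapply(ensemble$episodes, `[[`, TRUE, "failed")
  eps <- ensemble$episodes[ok]
  ee_map <- model$output_maps$ee
  term <- t(vapply(eps, function(ep) {
    x <- ep$states[, ncol(ep$states)]
    ee_map(x)[1:2]
  }, numeric(2)))
  muscle_names <- sub("^a_", "", model$labels[activation_rows])
  cci <- t(vapply(eps, function(ep) {
    A <- ep$states[activation_rows, , drop = FALSE]
    rownames(A) <- muscle_names
    vapply(pairs, function(pr) {
      af <- A[pr[1], ]; ax <- A[pr[2], ]
      mx <- pmax(af, ax)
      v <- ifelse(mx <= 0, 0, (pmin(af, ax) / mx) * (af + ax))
      mean(v)
    }, numeric(1))
  }, numeric(length(pairs))))
  corrective <- NULL
  if (!is.null(unperturbed_mean)) {
    devs <- lapply(eps, function(ep)
      ep$states[activation_rows, , drop = FALSE] - unperturbed_mean)
    arr <- simplify2array(devs)
    corrective <- list(mean = apply(arr, c(1, 2), mean),
                       sd = apply(arr, c(1, 2), stats::sd))
  }
  list(ellipse = confidence_ellipse(term),
       terminal_ee = term,
       terminal_sd = apply(term, 2, stats::sd),
       corrective = corrective,
       cci = cci, cci_mean = colMeans(cci),
       n_used = sum(ok))
}
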