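# Configuration parsing and result serialization.

fnv1a_hash <- function(obj) {
  txt <- paste(deparse(obj), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- (h + b) %% 4294967296          # mix byte (addition variant, keeps
    lo <- h %% 65536                    # the multiply exact in doubles)
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections `model`, `noise`, `task`, `solver`,
#' `output`. Missing entries fall back to the packaged defaults
#' (`balance_defaults()` / `reach_defaults()`); unknown keys are rejected
#' with the offending name. Quantities follow the printed table units at the
#' config boundary (degrees for balance sensory noise and platform rotation,
#' m/s^2 for translation, mm for reach sensory noise) and are converted to SI
#' internally, exactly once.
#'
#' @param path YAML file path.
#' @return object of class `run_config`: `model_kind`, `params` (full SI
#'   parameter list), `task` / `condition`, `solver`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("model", "noise", "task", "solver", "output")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("load_config: unknown section(s): ",
                        paste(bad, collapse = ", "))
  kind <- cfg$model$kind %||% "balance"
  if (!kind %in% c("balance", "reaching"))
    stop("load_config: model$kind must be 'balance' or 'reaching'")
  params <- if (kind == "balance") balance_defaults() else reach_defaults()

  mod <- cfg$model
  mod$kind <- NULL
  if (kind == "balance" && !is.null(mod)) {
    known <- c("mass", "length", "gravity", "inertia")
    bad <- setdiff(names(mod), c(known, "muscles", "geometry"))
    if (length(bad)) stop("load_config: unknown model key(s): ",
                          paste(bad, collapse = ", "))
    for (k in intersect(names(mod), known)) {
      v <- mod[[k]]
      if (!is.numeric(v) || v <= 0)
        stop("load_config: model$", k, " must be a positive number")
      params$pendulum[[k]] <- v
    }
    for (m in names(mod$muscles)) {
      for (f in names(mod$muscles[[m]])) {
        if (f == "f_iso_max" && mod$muscles[[m]][[f]] <= 0)
          stop("load_config: f_iso_max must be positive")
        params$muscles[[m]][[f]] <- mod$muscles[[m]][[f]]
      }
    }
    for (m in names(mod$geometry))
      params$geometry[[m]] <- utils::modifyList(params$geometry[[m]],
                                                mod$geometry[[m]])
  }
  if (kind == "reaching" && !is.null(mod) && length(mod)) {
    bad <- setdiff(names(mod), c("arm", "muscles", "geometry"))
    if (length(bad)) stop("load_config: unknown model key(s): ",
                          paste(bad, collapse = ", "))
    for (k in names(mod$arm)) {
      if (mod$arm[[k]] <= 0) stop("load_config: arm$", k, " must be positive")
      params$arm[[k]] <- mod$arm[[k]]
    }
  }

  noi <- cfg$noise
  if (!is.null(noi)) {
    if (kind == "balance") {
      bad <- setdiff(names(noi), c("sensory_sd_deg", "motor_sd",
                                   "rotation_sd_deg", "translation_sd"))
      if (length(bad)) stop("load_config: unknown noise key(s): ",
                            paste(bad, collapse = ", "))
      if (!is.null(noi$sensory_sd_deg)) {
        sd <- noi$sensory_sd_deg
        ok <- c("p_q", "p_qd", "v_q", "v_qd")
        bad <- setdiff(names(sd), ok)
        if (length(bad)) stop("load_config: unknown sensory channel: ",
                              paste(bad, collapse = ", "))
        for (k in names(sd))
          params$noise$sensory_psd[[k]] <- deg2rad(sd[[k]])^2
      }
      if (!is.null(noi$motor_sd))
        params$noise$motor_psd[] <- as.numeric(noi$motor_sd)^2
      if (!is.null(noi$rotation_sd_deg))
        params$noise$rotation_sd_deg <-
          utils::modifyList(params$noise$rotation_sd_deg, noi$rotation_sd_deg)
      if (!is.null(noi$translation_sd))
        params$noise$translation_sd <- as.numeric(noi$translation_sd)
    } else {
      bad <- setdiff(names(noi), c("sensory_sd_mm", "motor_sd_nm"))
      if (length(bad)) stop("load_config: unknown noise key(s): ",
                            paste(bad, collapse = ", "))
      if (!is.null(noi$sensory_sd_mm))
        params$noise$sensory_psd[] <- (as.numeric(noi$sensory_sd_mm) * 1e-3)^2
      if (!is.null(noi$motor_sd_nm))
        params$noise$motor_psd[] <- as.numeric(noi$motor_sd_nm)^2
    }
  }

  task <- cfg$task %||% list()
  condition <- NULL
  if (kind == "balance") {
    condition <- balance_condition(
      perturbation = task$perturbation %||% "none",
      magnitude_index = task$magnitude_index %||% 1L,
      sensory = task$sensory %||% "healthy",
      srs = isTRUE(task$srs))
  } else {
    task <- reach_task(kind = task$kind %||% "circle",
                       duration = task$duration %||% 0.8,
                       distance = task$distance %||% 0.25,
                       accuracy_sd_bound = (task$accuracy_sd_cm %||% 0.4) / 100,
                       ff_strength = task$ff_strength %||% 200)
  }

  solver <- utils::modifyList(
    list(seed = 1L, mesh_dt = params$mesh_dt, tol_con = 1e-8,
         max_iterations = 300L),
    cfg$solver %||% list())
  params$mesh_dt <- solver$mesh_dt

  structure(list(model_kind = kind, params = params,
                 task = if (kind == "reaching") task else NULL,
                 condition = condition,
                 solver = solver, output = cfg$output %||% list(),
                 hash = fnv1a_hash(list(kind, params, task, condition, solver))),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize results to JSON (+ CSV for per-node tables)
#'
#' Solutions are written as a JSON file holding the policy, objective,
#' status, constraint residuals and a config hash, plus a CSV per-node table
#' (time, mean state, upper-triangular covariance entries, feedforward
#' excitations, feedback gains) when a trajectory is present. Plain lists
#' (outcome measures) are written as a single JSON file. Field order is
#' deterministic.
#'
#' @param x `soc_solution`, `episode_ensemble`, or a plain list of outcomes.
#' @param path output path without extension (or with `.json`).
#' @param config_hash optional provenance hash embedded in the JSON.
#' @return invisible character vector of files written.
#' @export
write_results <- function(x, path, config_hash = NULL) {
  base <- sub("\\.json$", "", path)
  files <- character(0)
  if (inherits(x, "soc_solution")) {
    pol <- x$policy
    out <- list(kind = "soc_solution",
                objective = x$objective_value,
                status = x$status,
                constraint_residuals = x$constraint_residuals,
                e_ff = pol$e_ff, K = pol$K,
                times = pol$times,
                config_hash = config_hash)
    jsonlite::write_json(out, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    files <- paste0(base, ".json")
    if (!is.null(x$trajectory)) {
      tb <- trajectory_table(x)
      utils::write.csv(tb, paste0(base, ".csv"), row.names = FALSE)
      files <- c(files, paste0(base, ".csv"))
    }
  } else if (inherits(x, "episode_ensemble")) {
    rows <- lapply(seq_along(x$episodes), function(i) {
      ep <- x$episodes[[i]]
      data.frame(episode = i, time = ep$times,
                 t(ep$states), failed = ep$failed)
    })
    tb <- do.call(rbind, rows)
    utils::write.csv(tb, paste0(base, ".csv"), row.names = FALSE)
    files <- paste0(base, ".csv")
  } else {
    jsonlite::write_json(x, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    files <- paste0(base, ".json")
  }
  invisible(files)
}

# per-node table of a solution trajectory
trajectory_table <- function(sol) {
  traj <- sol$trajectory
  n <- length(traj$times)
  nstate <- ncol(traj$mean)
  ut <- which(upper.tri(traj$cov[[1]], diag = TRUE))
  covm <- t(vapply(traj$cov, function(P) P[ut], numeric(length(ut))))
  e_ff <- sol$policy$e_ff
  if (is.null(dim(e_ff))) e_ff <- matrix(e_ff, n, length(e_ff), byrow = TRUE)
  Kf <- sol$policy$K
  Kmat <- if (length(dim(Kf)) == 3L)
    t(apply(Kf, 3, as.numeric))
  else matrix(as.numeric(Kf), n, length(Kf), byrow = TRUE)
  df <- data.frame(time = traj$times, traj$mean, covm, e_ff, Kmat)
  names(df) <- c("time",
                 paste0("mean_", seq_len(nstate)),
                 paste0("cov_", ut),
                 paste0("eff_", seq_len(ncol(e_ff))),
                 paste0("K_", seq_len(ncol(Kmat))))
  df
}

#' Read back a serialized solution policy
#'
#' Round-trip counterpart of `write_results` for solutions: restores the
#' policy (feedforward, gains, mesh times), objective and status.
#'
#' @param path JSON path written by `write_results`.
#' @return list with `policy` (`control_policy`), `objective`, `status`.
#' @export
read_solution <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(js$kind, "soc_solution"))
    stop("read_solution: not a serialized soc_solution")
  K <- js$K
  if (!is.null(dim(K)) && length(dim(K)) == 3L) K <- aperm(K, c(1, 2, 3))
  list(policy = control_policy(e_ff = js$e_ff, K = K, times = js$times),
       objective = js$objective, status = js$status,
       config_hash = js$config_hash)
}
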