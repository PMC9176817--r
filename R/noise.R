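#' Noise source specification
#'
#' Container describing the independent zero-mean Gaussian disturbance sources
#' of a stochastic model by the diagonal of their continuous-time power
#' spectral density (PSD) matrix. Each source carries a label and a role:
#' `"sensory"` sources enter additively inside the feedback signal,
#' `"motor"` (system) sources enter the dynamics right-hand side, and
#' `"pinned"` sources are random constants whose stationary covariance is
#' imposed directly (used for the platform states of the balance model).
#'
#' @param psd numeric vector of PSD diagonal entries (units^2/Hz), all >= 0.
#' @param labels unique character labels, one per source.
#' @param role character vector, each one of "sensory", "motor", "pinned".
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(psd, labels, role) {
  psd <- as.numeric(psd)
  if (any(psd < 0)) stop("noise_spec: PSD entries must be non-negative")
  if (length(labels) != length(psd) || anyDuplicated(labels))
    stop("noise_spec: labels must be unique and complete")
  role <- match.arg(role, c("sensory", "motor", "pinned"), several.ok = TRUE)
  if (length(role) == 1L) role <- rep(role, length(psd))
  if (length(role) != length(psd))
    stop("noise_spec: one role per source required")
  structure(list(psd = psd, labels = labels, role = role),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> ", length(x$psd), " sources\n", sep = "")
  print(data.frame(label = x$labels, psd = x$psd, role = x$role))
  invisible(x)
}

# diagonal PSD matrix of a subset of sources
psd_matrix <- function(noise, roles = c("sensory", "motor")) {
  keep <- noise$role %in% roles
  diag(noise$psd[keep], nrow = sum(keep))
}

#' Discretize a continuous noise power spectral density
#'
#' Converts the PSD of a continuous-time white-noise source into the variance
#' of the equivalent discrete-time Gaussian sequence for an integration step
#' `dt`: variance = PSD / dt. With this scaling, Euler propagation of the
#' state covariance is invariant to the step size for linear systems (the
#' per-step increment `dt * (PSD/dt) * dt = PSD * dt` accumulates to
#' `PSD * t` independently of `dt`).
#'
#' @param psd_value continuous PSD (units^2/Hz), scalar or vector.
#' @param dt integration step in seconds, > 0.
#' @return discrete-time variance (units^2).
#' @export
discretize_noise <- function(psd_value, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("discretize_noise: dt must be a positive scalar")
  psd_value / dt
}
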