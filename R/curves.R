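# Hill-type muscle characteristic curves.
#
# Coefficients follow the widely used smooth parameterization of the active
# force-length (sum of Gaussians), force-velocity (log/arsinh form) and
# passive force-length (exponential) relationships common in direct-collocation
# musculoskeletal simulation. All expressions are complex-analytic so model
# right-hand sides can be differentiated by complex step.

.fl_b <- matrix(c(
  0.814483478343008, 1.055033428970575,  0.162384573599574, 0.063303448465465,
  0.433004984392647, 0.716775413397760, -0.029947116970696, 0.200356847296188,
  0.100000000000000, 1.000000000000000,  0.353553390593274, 0.000000000000000),
  nrow = 3, byrow = TRUE)

.fv_d <- c(-0.318323436899127, -8.149156043475250,
           -0.374121508647863,  0.885644059915004)

.fp_kpe <- 4.0
.fp_e0  <- 0.6

#' Muscle characteristic curve set
#'
#' @param fl_coeff 3 x 4 Gaussian coefficients of the active force-length
#'   curve (rows: components; columns b1..b4).
#' @param fv_coeff length-4 coefficients of the force-velocity curve.
#' @param fp_kpe,fp_e0 passive-curve shape and strain parameters.
#' @return object of class `muscle_curves`.
#' @export
muscle_curves <- function(fl_coeff = .fl_b, fv_coeff = .fv_d,
                          fp_kpe = .fp_kpe, fp_e0 = .fp_e0) {
  structure(list(fl = fl_coeff, fv = fv_coeff, kpe = fp_kpe, e0 = fp_e0),
            class = "muscle_curves")
}

#' Active force-length multiplier at normalized fiber length
#' @param lnorm normalized fiber length (1 = optimal).
#' @param curves `muscle_curves`.
#' @export
fl_active <- function(lnorm, curves = muscle_curves()) {
  b <- curves$fl
  out <- 0
  for (i in 1:3) {
    den <- b[i, 3] + b[i, 4] * lnorm
    out <- out + b[i, 1] * exp(-0.5 * (lnorm - b[i, 2])^2 / (den * den))
  }
  out
}

#' Force-velocity multiplier at normalized fiber velocity
#' @param vnorm fiber velocity normalized by (optimal length x maximal
#'   contraction velocity); negative = shortening.
#' @param curves `muscle_curves`.
#' @export
fv_mult <- function(vnorm, curves = muscle_curves()) {
  d <- curves$fv
  u <- d[2] * vnorm + d[3]
  d[1] * log(u + sqrt(u * u + 1)) + d[4]
}

#' Passive force-length multiplier
#' @inheritParams fl_active
#' @export
fp_passive <- function(lnorm, curves = muscle_curves()) {
  (exp(curves$kpe * (lnorm - 1) / curves$e0) - 1) / (exp(curves$kpe) - 1)
}
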