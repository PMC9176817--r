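#' Complex-step Jacobian
#'
#' Machine-precision first derivatives of a smooth vector function obtained by
#' evaluating it at complex arguments `x + ih e_j` and taking `Im(f)/h`. Unlike
#' finite differences there is no subtractive cancellation, so the step can be
#' taken far below sqrt(machine eps) and the result is exact to roundoff. All
#' model right-hand sides in this package are written with complex-analytic
#' primitives (polynomials, exp, log, sin, cos, sqrt) so that they can be
#' differentiated this way; this plays the role automatic differentiation plays
#' in compiled optimal-control toolchains.
#'
#' @param f function taking a numeric (or complex) vector, returning a vector
#'   of fixed length. Must not branch on its argument's value except through
#'   `Re()` gates that are locally constant.
#' @param x point of evaluation (numeric vector).
#' @param h imaginary step (default 1e-20).
#' @return numeric Jacobian matrix `length(f(x))` x `length(x)`.
#' @export
cs_jacobian <- function(f, x, h = 1e-20) {
  x <- as.numeric(x)
  f0 <- f(x)
  m <- length(f0)
  n <- length(x)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    xj <- as.complex(x)
    xj[j] <- xj[j] + complex(imaginary = h)
    J[, j] <- Im(f(xj)) / h
  }
  J
}

#' Complex-step gradient of a scalar function
#' @inheritParams cs_jacobian
#' @return numeric gradient vector.
#' @export
cs_grad <- function(f, x, h = 1e-20) {
  as.numeric(cs_jacobian(function(z) f(z)[1L], x, h = h))
}

# Real part of possibly-complex input; used to gate branches so that the
# branch choice is locally constant under complex-step perturbation.
re_part <- function(x) if (is.complex(x)) Re(x) else x

# Smooth positive part: (x + sqrt(x^2 + eps))/2. Complex-analytic, >= 0 for
# real x up to O(sqrt(eps)); used to keep optimizer parameterizations smooth.
softplus_sqrt <- function(x, eps = 1e-10) 0.5 * (x + sqrt(x * x + eps))
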