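# Polynomial helpers. Coefficients are stored in ascending order
# (c0 + c1*x + c2*x^2 + ...), matching the JSON interchange format.

#' Evaluate a polynomial (ascending coefficients) by Horner's scheme
#' @param coeffs numeric vector, ascending powers
#' @param x numeric vector of evaluation points
#' @return numeric vector of the same length as `x`
#' @keywords internal
#' @noRd
poly_eval <- function(coeffs, x) {
  n <- length(coeffs)
  if (n == 0L) return(rep(0, length(x)))
  acc <- rep(coeffs[n], length(x))
  if (n > 1L) {
    for (i in seq(n - 1L, 1L)) acc <- acc * x + coeffs[i]
  }
  acc
}

#' Derivative of a polynomial in ascending-coefficient form
#' @keywords internal
#' @noRd
poly_deriv <- function(coeffs) {
  n <- length(coeffs)
  if (n <= 1L) return(0)
  coeffs[-1L] * seq_len(n - 1L)
}

#' Sum of two polynomials of possibly different degree
#' @keywords internal
#' @noRd
poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}
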