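# Phase resetting curve (PRC) models.
#
# Phase convention: phases live in [0, 1), growing linearly between spikes.
# A positive resetting value is a delay (the perturbed cycle is lengthened),
# a negative value an advance. Causality bounds every resetting from below by
# phi - 1: an input cannot advance the next spike to before its own arrival.
# The bound appears in excitatory PRCs as a linear branch f(phi) = phi - 1
# with slope one near the end of the cycle, where an input almost immediately
# evokes a spike.

#' Construct a PRC model
#'
#' A PRC model is a polynomial approximation of the mean phase resetting
#' together with polynomial envelopes one standard deviation above and below
#' the mean, a Type I/II label, and the coupling sign of the synapse it was
#' measured with. Evaluation clamps the mean to the causal limit
#' `f(phi) >= phi - 1`.
#'
#' @param mean_coeffs numeric vector of polynomial coefficients for the mean
#'   resetting curve, ascending powers of phase.
#' @param sigma_upper_coeffs,sigma_lower_coeffs coefficients of the
#'   mean+sigma and mean-sigma envelope polynomials. Default to
#'   `mean_coeffs` (zero noise).
#' @param coupling_sign `"excitatory"` or `"inhibitory"`.
#' @param prc_type optional `"I"` or `"II"`; computed from the sign pattern
#'   of the mean curve when missing (see [classify_prc()]).
#' @return an object of class `prc_model`.
#' @export
#' @examples
#' m <- prc_model(c(0, -1.2, 1.2), coupling_sign = "excitatory")
#' evaluate_prc(m, c(0.1, 0.5, 0.95))
prc_model <- function(mean_coeffs,
                      sigma_upper_coeffs = mean_coeffs,
                      sigma_lower_coeffs = mean_coeffs,
                      coupling_sign = c("excitatory", "inhibitory"),
                      prc_type = NULL) {
  coupling_sign <- match.arg(coupling_sign)
  stopifnot(is.numeric(mean_coeffs), length(mean_coeffs) >= 1L,
            all(is.finite(mean_coeffs)),
            is.numeric(sigma_upper_coeffs), is.numeric(sigma_lower_coeffs))
  model <- structure(
    list(
      mean_coeffs = as.numeric(mean_coeffs),
      sigma_upper_coeffs = as.numeric(sigma_upper_coeffs),
      sigma_lower_coeffs = as.numeric(sigma_lower_coeffs),
      coupling_sign = coupling_sign,
      prc_type = NA_character_,
      endpoint_values = c(f0 = NA_real_, f1 = NA_real_)
    ),
    class = "prc_model"
  )
  model$endpoint_values <- c(
    f0 = unname(evaluate_prc(model, 0)),
    f1 = unname(prc_endpoint_late(model))
  )
  model$prc_type <- if (is.null(prc_type)) classify_prc(model) else
    match.arg(prc_type, c("I", "II"))
  model
}

#' @export
print.prc_model <- function(x, ...) {
  cat(sprintf("<prc_model> %s Type %s, degree %d\n",
              x$coupling_sign, x$prc_type, length(x$mean_coeffs) - 1L))
  cat("  mean coeffs: ", paste(signif(x$mean_coeffs, 4), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  endpoints f(0+) = %.4g, f(1-) = %.4g (gap %.4g)\n",
              x$endpoint_values[["f0"]], x$endpoint_values[["f1"]],
              prc_endpoint_gap(x)))
  invisible(x)
}

check_phase <- function(phase) {
  if (!is.numeric(phase) || any(!is.finite(phase)) ||
      any(phase < 0) || any(phase >= 1)) {
    stop("`phase` must lie in [0, 1)", call. = FALSE)
  }
  phase
}

#' Evaluate the mean phase resetting at given phases
#'
#' Returns the polynomial mean resetting with the causal limit enforced as a
#' floor: `max(polynomial(phase), phase - 1)`.
#'
#' @param model a [prc_model()].
#' @param phase numeric vector of phases in `[0, 1)`.
#' @return numeric vector of resetting values (positive = delay).
#' @export
evaluate_prc <- function(model, phase) {
  check_phase(phase)
  pmax(poly_eval(model$mean_coeffs, phase), phase - 1)
}

# TRUE where the causal limit is active. The junction point itself counts as
# clamped so that slopes at the junction are reported from the causal side.
prc_clamped <- function(model, phase) {
  poly_eval(model$mean_coeffs, phase) <= phase - 1
}

#' Slope of the effective (clamped) PRC
#'
#' On the causal-limit branch the slope is exactly 1; at the clamp junction
#' the causal-limit-side slope is reported. Positive slopes at a locking
#' point are stabilizing, negative slopes destabilizing.
#'
#' @inheritParams evaluate_prc
#' @return numeric vector of slopes (dimensionless).
#' @export
prc_slope <- function(model, phase) {
  check_phase(phase)
  s <- poly_eval(poly_deriv(model$mean_coeffs), phase)
  s[prc_clamped(model, phase)] <- 1
  s
}

#' Phase-dependent noise amplitude sigma(phase)
#'
#' Half the distance between the upper and lower envelope polynomials,
#' floored at zero.
#'
#' @inheritParams evaluate_prc
#' @return numeric vector of standard deviations (dimensionless resetting).
#' @export
prc_sigma <- function(model, phase) {
  check_phase(phase)
  pmax((poly_eval(model$sigma_upper_coeffs, phase) -
          poly_eval(model$sigma_lower_coeffs, phase)) / 2, 0)
}

# Effective value as phase -> 1-: the causal floor tends to 0-, so negative
# polynomial endpoints are reported as 0 (they are unobservable), positive
# ones (inhibitory delays that "do not return to zero") survive.
prc_endpoint_late <- function(model) {
  max(poly_eval(model$mean_coeffs, 1), 0)
}

#' Endpoint discontinuity f(1-) - f(0+) of the effective PRC
#'
#' Strong inhibition measured just before an expected spike delays the next
#' spike much more than the same input just after a spike, leaving a gap
#' between the late and early ends of the PRC. A positive gap destabilizes
#' zero-delay synchrony regardless of the PRC slope.
#'
#' @inheritParams evaluate_prc
#' @return a single number, `>= 0` for the canonical templates.
#' @export
prc_endpoint_gap <- function(model) {
  unname(model$endpoint_values[["f1"]] - model$endpoint_values[["f0"]])
}

#' Classify a PRC as Type I or Type II
#'
#' Type I PRCs consist of all advances or all delays; Type II PRCs mix the
#' two. The label is read off the sign pattern of the effective mean curve on
#' a fine grid over (0.05, 0.95): the curve is Type II when each sign
#' persists, above 2% of the curve's amplitude, over at least 3% of the
#' cycle. The width and amplitude floors keep the decision sensitive to the
#' weak lobes of genuinely Type II curves (which span >8% of the cycle in
#' measured cells) while discounting two fitting artifacts: coefficient
#' noise at the phase endpoints, and the systematic late-phase delay bias of
#' measured excitatory PRCs (advances longer than the remaining cycle
#' fraction cannot be observed, so means near phase one are pushed toward
#' small spurious delays). An identically zero curve is Type I by
#' convention.
#'
#' @param model a [prc_model()].
#' @return `"I"` or `"II"`.
#' @export
classify_prc <- function(model) {
  grid <- seq(0.05, 0.95, length.out = 901)
  step <- grid[2] - grid[1]
  v <- evaluate_prc(model, grid)
  amp <- max(abs(v))
  if (amp == 0) return("I")
  thr <- 0.02 * amp
  pos_width <- sum(v > thr) * step
  neg_width <- sum(v < -thr) * step
  if (pos_width >= 0.03 && neg_width >= 0.03) "II" else "I"
}

#' Draw a noisy phase resetting value
#'
#' Gaussian draw with mean `evaluate_prc(model, phase)` and standard
#' deviation `prc_sigma(model, phase)`. Draws violating causality (a spike
#' before the input that reset it, `f < phase - 1`) are rejected and redrawn,
#' truncating the distribution near the causal limit.
#'
#' @inheritParams evaluate_prc
#' @param max_draws rejection bound per element; exceeding it signals an
#'   inconsistent noise envelope.
#' @return numeric vector of resetting values, all `>= phase - 1`.
#' @export
sample_noisy_resetting <- function(model, phase, max_draws = 1000L) {
  check_phase(phase)
  m <- evaluate_prc(model, phase)
  s <- prc_sigma(model, phase)
  out <- m
  todo <- s > 0
  out[todo] <- NA_real_
  floor_ <- phase - 1
  draws <- 0L
  while (any(todo)) {
    draws <- draws + 1L
    if (draws > max_draws) {
      stop("rejection sampling exceeded ", max_draws,
           " draws: noise envelope inconsistent with the causal limit",
           call. = FALSE)
    }
    cand <- stats::rnorm(sum(todo), m[todo], s[todo])
    ok <- cand >= floor_[todo]
    idx <- which(todo)[ok]
    out[idx] <- cand[ok]
    todo[idx] <- FALSE
  }
  out
}
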