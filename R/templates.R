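# Canonical PRC templates and synthetic measurement/circuit generators.
#
# Four archetypes cover what is typically measured in entorhinal stellate and
# pyramidal cells with virtual AMPA- or GABAA-like synapses:
#   exc_I  : advances only, single interior extremum, ~0 at both endpoints.
#   exc_II : weakly Type II - a small delay lobe at early phases (< ~0.15),
#            advances elsewhere.
#   inh_I  : delays only, monotonically increasing with phase, not returning
#            to zero as phase -> 1.
#   inh_II : weakly Type II - small advances at early phases, delays
#            elsewhere, nonzero late endpoint.
# Excitatory templates carry a noise envelope that shrinks at late phases
# (inputs near the causal limit trigger spikes reliably); inhibitory noise is
# roughly phase-independent.

template_names <- c("exc_I", "exc_II", "inh_I", "inh_II")

# Shape constants, fixed once:
# exc_II root structure phi*(phi-r)*(phi-1); its minimum depth on (0,1) for
# r = 0.15 normalizes the amplitude.
.exc2_root <- 0.15
.exc2_depth <- 0.115524  # |min of phi*(phi-0.15)*(phi-1)| on (0,1)
# inh_II quartic (ascending coefficients, zero constant term): small advance
# lobe at early phases (minimum -0.025 at phi = 0.12, ~6% of the late delay
# amplitude), slope turning positive near 0.10 so zero-delay and very
# short-delay synchrony are destabilized while synchrony at locking phases
# above ~0.12 is stable, zero crossing at 0.22, a gentle mid-cycle rise
# (f(0.5) = 0.08; the shallow slope there makes the near-synchronous locking
# visibly sensitive to period heterogeneity, which pins the leading neuron),
# and a nonzero late endpoint f(1-) = 0.45 (the discontinuity of strong
# inhibition).
.inh2_coeffs <- c(0, -0.6232162136, 4.3265155459, -7.7870331423,
                  4.5337338100)
.inh2_gap <- 0.45  # natural endpoint gap of the canonical (scale 0.3) shape

# Default noise envelopes (resetting units)
.sigma_exc <- c(0.10, -0.08)  # 0.10*(1 - 0.8*phase): late-phase reduction
.sigma_inh <- c(0.015)        # flat (weakly phase-dependent in the data)

#' Build a canonical PRC template
#'
#' Returns a [prc_model()] realizing one of the four archetype shapes with a
#' polynomial mean curve and the matching noise envelope (decreasing toward
#' late phases for excitation, flat for inhibition).
#'
#' @param name one of `"exc_I"`, `"exc_II"`, `"inh_I"`, `"inh_II"`.
#' @param scale resetting amplitude (maximum |mean resetting| of the shape
#'   before causal clamping), `> 0` (or 0 for a degenerate zero curve).
#' @param endpoint_gap inhibitory templates only: effective discontinuity
#'   `f(1-) - f(0+)`. Defaults: `0.3 * scale` for `inh_I` (for a monotone
#'   curve the gap is the amplitude), the shape's natural value
#'   (`1.5 * scale`) for `inh_II`. Ignored for excitatory templates.
#' @param noise `TRUE` attaches the default noise envelope; `FALSE` gives a
#'   noiseless model.
#' @return a [prc_model()].
#' @export
#' @examples
#' tpl <- make_template("exc_II", scale = 0.3)
#' classify_prc(tpl)  # "II"
make_template <- function(name, scale = 0.3, endpoint_gap = NULL,
                          noise = TRUE) {
  if (!name %in% template_names) {
    stop("unknown template '", name, "'; use one of ",
         paste(template_names, collapse = ", "), call. = FALSE)
  }
  stopifnot(scale >= 0)
  mean_c <- switch(name,
    # -4*s*phi*(1-phi): pure advances, minimum -s at phi = 0.5
    exc_I = c(0, -4 * scale, 4 * scale),
    # (s/depth)*phi*(phi-r)*(phi-1): small delay lobe below r, advances after
    exc_II = (scale / .exc2_depth) *
      c(0, .exc2_root, -(1 + .exc2_root), 1),
    # G*phi^2: monotone delays rising to the endpoint gap
    inh_I = {
      gap <- if (is.null(endpoint_gap)) 0.3 * scale else endpoint_gap
      stopifnot(gap >= 0)
      c(0, 0, gap)
    },
    # canonical quartic, rescaled if an explicit endpoint gap is given
    inh_II = {
      mult <- if (is.null(endpoint_gap)) scale / 0.3 else {
        stopifnot(endpoint_gap >= 0)
        endpoint_gap / .inh2_gap
      }
      .inh2_coeffs * mult
    }
  )
  sig <- if (startsWith(name, "exc")) .sigma_exc else .sigma_inh
  if (!noise) sig <- 0
  prc_model(
    mean_coeffs = mean_c,
    sigma_upper_coeffs = poly_add(mean_c, sig),
    sigma_lower_coeffs = poly_add(mean_c, -sig),
    coupling_sign = if (startsWith(name, "exc")) "excitatory" else "inhibitory"
  )
}

#' Generate a synthetic PRC measurement set
#'
#' Emulates the dynamic-clamp stimulation protocol: stimulus phases are drawn
#' uniformly on `[0, 1)` and each resetting value is a causality-respecting
#' Gaussian draw around the model mean with the model's phase-dependent
#' standard deviation (see [sample_noisy_resetting()]).
#'
#' @param model a [prc_model()].
#' @param n_samples number of (phase, resetting) records, `>= 300`.
#' @param seed optional integer seed for reproducibility.
#' @param intrinsic_period nominal free-running period, ms.
#' @return a [prc_measurements()] set.
#' @export
generate_measurements <- function(model, n_samples = 2000L, seed = NULL,
                                  intrinsic_period = 100) {
  stopifnot(inherits(model, "prc_model"), n_samples >= 300L)
  if (!is.null(seed)) set.seed(seed)
  phase <- stats::runif(n_samples)
  resetting <- sample_noisy_resetting(model, phase)
  prc_measurements(phase, resetting,
                   coupling_sign = model$coupling_sign,
                   intrinsic_period = intrinsic_period)
}

#' Construct a two-neuron circuit specification
#'
#' Two reciprocally pulse-coupled oscillators with conduction delays. The
#' second period is `period_a * (1 + heterogeneity)` and a delay difference
#' `delta_delay` is split symmetrically across the two directions:
#' `delay_12 = delay + delta_delay/2` (neuron 1 to neuron 2) and
#' `delay_21 = delay - delta_delay/2`.
#'
#' @param prc_a,prc_b [prc_model()]s for the two neurons (same coupling
#'   sign).
#' @param period_a intrinsic period of neuron 1, ms.
#' @param heterogeneity fractional period difference, `|h| < 0.5`; 0.04 is a
#'   typical value for deliberately detuned circuits.
#' @param delay mean conduction delay, ms, `>= 0`.
#' @param delta_delay difference between directional delays, ms.
#' @return object of class `circuit_spec` with fields `P1`, `P2`, `prc1`,
#'   `prc2`, `delay_12`, `delay_21`, `coupling_sign`.
#' @export
make_circuit <- function(prc_a, prc_b = prc_a, period_a = 100,
                         heterogeneity = 0, delay = 0, delta_delay = 0) {
  stopifnot(inherits(prc_a, "prc_model"), inherits(prc_b, "prc_model"),
            period_a > 0, abs(heterogeneity) < 0.5, delay >= 0)
  if (prc_a$coupling_sign != prc_b$coupling_sign) {
    stop("both PRCs must share one coupling sign", call. = FALSE)
  }
  d12 <- delay + delta_delay / 2
  d21 <- delay - delta_delay / 2
  if (d12 < 0 || d21 < 0) {
    stop("`delta_delay` makes a directional delay negative", call. = FALSE)
  }
  structure(
    list(
      P1 = period_a,
      P2 = period_a * (1 + heterogeneity),
      prc1 = prc_a,
      prc2 = prc_b,
      delay_12 = d12,
      delay_21 = d21,
      coupling_sign = prc_a$coupling_sign
    ),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf(
    "<circuit_spec> %s, P = (%g, %g) ms, delays 1->2 %g ms / 2->1 %g ms\n",
    x$coupling_sign, x$P1, x$P2, x$delay_12, x$delay_21))
  invisible(x)
}
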