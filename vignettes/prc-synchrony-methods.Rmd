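---
title: "Predicting synchrony of delay-coupled neuronal oscillators from phase resetting curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synchrony of delay-coupled neuronal oscillators from phase resetting curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(prcsync)
```

## The model

Two neurons firing rhythmically (periods $P_1, P_2$, typically 80–140 ms for
theta-band entorhinal cells) are coupled reciprocally by brief synaptic
pulses that travel with conduction delays $\delta_{12}, \delta_{21}$. Each
neuron is treated as a limit-cycle oscillator whose response to a single
input is fully captured by its phase resetting curve (PRC)

$$f(\varphi) = \frac{P_j - P_i}{P_i},$$

the normalized change of the cycle containing an input delivered at phase
$\varphi = t_s/P_i \in [0,1)$. Positive resetting is a delay of the next
spike, negative an advance. Causality bounds every PRC from below:
$f(\varphi) \ge \varphi - 1$, with equality on the *causal limit* where an
excitatory input fires the cell immediately; on that branch the effective
PRC is linear with slope one.

The assumptions this inherits: each cell remains a pacemaker inside the
circuit; the effect of one input dies out before the next arrives (so phase
is well defined at each arrival); and inputs inside the closed loop resemble
the open-loop stimuli used to measure the PRC. Pulsatile coupling is the
essential abstraction — the synaptic conductance waveform itself is not
modeled.

## Fitting PRCs from noisy measurements

`fit_prc()` reproduces the standard measurement pipeline: samples are
divided into 100 equal-width phase bins, bins with fewer than 3 values are
expanded symmetrically into their neighbors, and polynomials of degree 2–4
are fit to the binned means. Degree selection uses AIC on the binned means
(for nested least-squares fits the in-sample error can never favor the lower
degree, so parsimony needs a penalized criterion; ties go to the lower
degree). Envelope polynomials of the same degree fit to mean $\pm$ sd give
the phase-dependent noise model $\sigma(\varphi)$, floored at zero.

Two data artifacts receive special handling, both consequences of the causal
limit. First, advances longer than the remaining cycle fraction cannot be
observed, which biases late-phase measurements toward small spurious delays;
for excitatory fits, positive resetting at phases above 0.9 is therefore
dropped (threshold exposed as `spurious_late_phase`). Second,
`classify_prc()` labels a curve Type II (mixed advances and delays) only
when each sign persists above 2% of the curve's amplitude over at least 3%
of the cycle on $(0.05, 0.95)$ — weak lobes of genuinely Type II cells span
far more than that, while endpoint fitting noise and the late-phase bias do
not.

## The synthetic templates

Since every downstream stage needs PRCs with controlled shape,
`make_template()` provides four canonical archetypes (all amplitudes default
to `scale = 0.3`, a mid-range value for 0.5–6 nS synaptic conductances):

```{r templates, eval = FALSE}
phi <- seq(0, 0.999, length.out = 400)
curves <- do.call(rbind, lapply(c("exc_I", "exc_II", "inh_I", "inh_II"),
  function(nm) data.frame(template = nm, phi = phi,
                          f = evaluate_prc(make_template(nm), phi))))
ggplot2::ggplot(curves, ggplot2::aes(phi, f)) +
  ggplot2::geom_line() +
  ggplot2::geom_abline(slope = 1, intercept = -1, linetype = 3) +
  ggplot2::facet_wrap(~template)
```

* `exc_I`: $-4s\,\varphi(1-\varphi)$ — all advances, single extremum,
  zero at the endpoints. Beyond $\varphi = 5/6$ the parabola dips under the
  causal limit, so the effective curve ends in the slope-one branch.
* `exc_II`: $\frac{s}{0.1155}\varphi(\varphi-0.15)(\varphi-1)$ — a weak
  delay lobe below $\varphi = 0.15$ (about 4.5% of the amplitude), advances
  elsewhere; clamped to the causal limit from $\varphi \approx 0.7$.
* `inh_I`: $G\varphi^2$ — delays increasing monotonically with phase. A
  monotone curve's endpoint value *is* its amplitude, so the endpoint gap
  parameter and the amplitude coincide (default $G = 0.3\,\mathrm{scale}$).
* `inh_II`: a quartic with a small advance lobe (minimum $-0.025$ near
  $\varphi = 0.10$), zero crossing at $0.22$, a gentle rise through
  mid-cycle ($f(0.5) = 0.08$) and a late delay of $0.45$ that does not
  return to zero — the endpoint discontinuity of strong inhibition.

The `inh_II` shape deserves its own paragraph, because the fitted curves it
stands in for are not published and its free constants had to be pinned down
by the circuit-level behavior reported for inhibitory Type II pairs. Those
constraints are: synchrony is unstable at very short normalized delays
(slope negative below $\varphi \approx 0.10$) but stable above
$\approx 0.12$; antiphase coexists with synchrony over short-to-intermediate
delays and disappears by $\delta/P \approx 0.3$; the antiphase time lags sit
near $\pm 0.6$ of the slower period (fixing the late amplitude); and 4%
period heterogeneity makes one neuron lead consistently in the
near-synchronous mode *without* destroying the bistability. The last pair of
facts jointly constrain the mid-cycle slope: the heterogeneity-induced lag
$\varepsilon \propto 1/f'$ must exceed the noise-driven lag spread (leader
pinning) while $(\delta - \varepsilon)/P$ stays inside the positive-slope
region (bistability survives). A spec of lobe depth, zero crossing,
mid-cycle value and endpoint uniquely determines the quartic; the chosen
constants satisfy all of the above simultaneously.

Noise envelopes: excitatory $\sigma(\varphi) = 0.10(1 - 0.8\varphi)$ — the
variability of excitatory resetting shrinks at late phases, where inputs
near the causal limit trigger spikes reliably; inhibitory
$\sigma = 0.015$, phase-independent. The inhibitory amplitude is the second
calibrated constant: above $\approx 0.02$ the lag noise swamps the
heterogeneity lag and the leader no longer pins. `sample_noisy_resetting()`
rejects draws violating causality, which truncates the distribution near the
causal limit — generated data inherit the same late-phase delay bias as real
measurements, which is deliberate.

What the generator does **not** emulate: membrane potentials, conductance
kinetics, spike-rate adaptation, slow drift of the intrinsic period, or
resetting that appears in the second cycle after an input. Tests passing on
synthetic data therefore validate the computational pipeline under the pulse
coupling assumptions, not those assumptions themselves.

## Existence of 1:1 lockings

In a 1:1 locking each neuron receives one input per cycle at a fixed phase
$\varphi_i$, giving stimulus and recovery intervals
$ts_i = P_i\varphi_i$ and $tr_i = P_i(1 - \varphi_i + f_i(\varphi_i))$.
A spike's influence returns to the emitting neuron through the loop after
$k$ cycles ($k = 1, 2, \dots$), which imposes two periodicity constraints:

$$\delta_{12} + \delta_{21} + tr_1(\varphi_1) = ts_2(\varphi_2) + (k-1)P_{N},
\qquad
\delta_{12} + \delta_{21} + tr_2(\varphi_2) = ts_1(\varphi_1) + (k-1)P_{N},$$

with network period $P_N = ts_i + tr_i$ (adding the two constraints shows a
simultaneous solution automatically equalizes the two neurons' periods).
`interval_curves()` exposes the graphical form: one curve per neuron with
abscissa and ordinate swapped for one of them, intersections = lockings.
`find_lockings()` solves the system by a sign-change scan of both residuals
on an $800 \times 800$ phase grid (the residuals are separable, so the scan
is two outer products), refines each candidate cell by damped Newton with
the analytic Jacobian to $|r| < 10^{-10} P_{\text{slow}}$, deduplicates
across $k$, and derives lags from $tl_1 = (ts_1 - \delta_{21}) \bmod P_N$,
$tl_2 = P_N - tl_1$. Degenerate circuits whose residual vanishes along a
curve rather than at points (two identical uncoupled cells) are flagged
rather than enumerated. Roots pinned exactly at $\varphi = 0$ sit on the
scan boundary and are not returned; the zero-delay synchronous state is
instead assessed directly via `assess_stability()` on the synchronous
candidate.

Modes are classified by their lags: synchrony when
$\min(tl)/P_N < 0.02$, antiphase when $|tl_1 - tl_2|/P_N < 0.02$ (the 0.02
matches the standard sweep increment), leader/follower when the short lag
approximates the conduction delay.

## Stability

The cobweb construction on the two interval curves gives the general
criterion: with $s_i = f_i'(\varphi_i)$ the locking is stable iff

$$|(1 - s_1)(1 - s_2)| < |(1 + (k-1)s_1)(1 + (k-1)s_2)|.$$

Positive slopes at the locking points are stabilizing, negative ones
destabilizing; for $k = 1$ the criterion reduces to
$|(1-s_1)(1-s_2)| < 1$. Synchronous modes face a stricter test, because a
perturbation from synchrony engages both inputs within the same cycle:
$|1 - (s_1 + s_2)| < 1$, so very large positive slopes also destabilize.
Two overrides complete the verdict:

* **Causal limit.** With both locking points on the slope-one branch the
  synchrony criterion sits exactly on its boundary — neutral stability in
  theory. Physically some latency always remains between the leader's spike
  and the one it evokes, so such modes are reported stable and flagged
  `neutral_at_limit`.
* **Endpoint discontinuity.** A strong inhibitory PRC with
  $f(1^-) > f(0^+)$ destabilizes zero-delay synchrony regardless of slope:
  the neuron that fires marginally late receives the strongly delaying
  late-phase input and falls further behind. The rule triggers for
  inhibitory models with a detected gap when the synchronous locking phase
  lies within 0.02 of 0 or 1; a short conduction delay moves the locking
  point off the discontinuity and returns the verdict to the slope
  criterion.

`delay_sweep()` applies all of this over a grid of delays normalized by the
slower neuron's period (increment 0.02 by default) and emits signed
normalized lags for bifurcation-style diagrams.

## Heterogeneity and the near-synchronous lag

Small period differences $\Delta P = P_1 - P_2$ and delay differences
$\Delta\delta = \delta_{12} - \delta_{21}$ perturb synchrony into a locking
with lag $\varepsilon$ (neuron 2 behind neuron 1). Writing both locking
phases near the homogeneous point $\varphi^* = \bar\delta/\bar P$ and
linearizing both PRCs there, the locking condition
$P_1(1 + f(\varphi_1)) = P_2(1 + f(\varphi_2))$ gives

$$\varepsilon = \frac{\Delta\delta}{2}
 - \Delta P\,\frac{1 + f(\varphi^*) - \varphi^* f'(\varphi^*)}
                  {2 f'(\varphi^*)}.$$

Identical neurons with equal delays lock exactly in phase. On the causal
limit ($f = \varphi - 1$, $f' = 1$) the numerator vanishes *identically*,
whatever the period difference — near-causal-limit synchrony is robust to
heterogeneity, and the lag reduces to $\Delta\delta/2$ exactly
(`heterogeneity_lag()` returns these limits exactly, computing the clamped
numerator symbolically rather than in floating point). The expression is
valid while the perturbed locking points stay in a linear neighborhood; the
package's own cross-check against the zero-noise map at 4% heterogeneity
agrees to a few percent.

## The noisy event-driven map

`run_map()` iterates the circuit event by event with no predetermined
firing order. The next event is whichever comes first: a spike (interval
$P_j(1-\varphi_j)$) or the arrival of a queued pulse (emission time plus
conduction delay). A spike resets its neuron's phase to zero and enqueues an
emission; an arrival subtracts the (optionally noisy) resetting from the
target's phase, and an arrival that carries the phase to 1 — the causal
limit — fires the target immediately. Numerical choices, each exposed or
documented:

* Simultaneous spike/arrival: the spike is processed first, so the input
  acts at phase 0 of the new cycle (`simultaneous = "after"`; `"before"` is
  available for probing the discontinuity mechanism, where the order of the
  two coincident events is exactly what is at stake).
* Multiple queued arrivals apply in arrival order.
* Phases pushed below 0 by a strong delaying input are queried at phase 0
  for subsequent arrivals (counted in the diagnostics); the spike interval
  handles negative phases naturally.
* Burn-in: 200 cycles discarded by default; 5000 cycles retained for
  histogram work.
* Noise: the same Gaussian-with-rejection draw as the measurement
  generator, so the map inherits the fitted mean *and* envelope.

Per-cycle lags are taken from each neuron-1 spike to the *next* neuron-2
spike wherever it falls: in near-synchrony the lag then hops between ~0 and
~$P_N$ as the leader switches, producing the characteristic wrap peaks at
$\pm$ one network period in the signed histograms. Only lags exceeding 1.5
median periods (a skipped cycle, i.e. a true doublet) are excluded, with a
counter.

`lag_histogram()` bins the signed lags ($tl_1$ positive, $tl_2$ negative)
normalized by the mean network period, so synchrony peaks at $0, \pm 1$ and
antiphase at $\pm \approx 0.5$. Normalization by the mean *network* period
rather than the slower intrinsic period keeps the wrap peaks at $\pm 1$
even for inhibitory circuits whose network period exceeds the intrinsic one
by ~15–40%; the intrinsic-period convention remains available via
`normalize = "slower"`. `count_lag_peaks()` reports local maxima of the
lightly smoothed counts above 5% of the tallest bin.

**Sampling bistability.** In a bistable regime a single noisy trajectory
stays in the basin it starts in: the zero-noise basin boundary (the edge of
the synchronous basin sits near lag $= \delta$) lies several lag standard
deviations from either locked state at realistic noise. The published
five-peak bistable histograms are therefore sampled here by pooling
independent runs from random initial phases (`run_map_ensemble()`, default
12 runs x 400 cycles), which is also how bistability is probed
experimentally — either mode can be observed depending on initial
conditions. Within-run noise still generates the leader-switching wrap
peaks.

## Circular statistics

`circular_summary()` maps each lag to an angle
$\theta_k = 2\pi\,tl_k/\bar P_N$, pooling both directions ($tl_1/P_N$ and
$1 - tl_2/P_N$ coincide for a perfect locking). $X$ and $Y$ are the *means*
of $\cos\theta$ and $\sin\theta$ — this normalization is forced by the
reported range of locking strengths, $R^2 = X^2 + Y^2 \in [0,1]$ — and the
mean network phase is $\operatorname{atan2}(Y, X)/2\pi \bmod 1$. A zero
resultant leaves the phase undefined (`NA`). For reporting, `wrap_phase()`
recenters phases on $(-0.25, 0.75]$ so near-zero phases do not oscillate
between $0^+$ and $1^-$ across seeds.

## A worked delay sweep

```{r sweep, eval = FALSE}
circ <- make_circuit(make_template("exc_I", noise = FALSE), period_a = 1)
sw <- delay_sweep(circ, stable_only = TRUE)
ggplot2::ggplot(sw, ggplot2::aes(delay_norm)) +
  ggplot2::geom_point(ggplot2::aes(y = tl1_norm), shape = 4) +
  ggplot2::geom_point(ggplot2::aes(y = tl2_norm), shape = 4) +
  ggplot2::geom_point(ggplot2::aes(y = period_norm), color = "grey60") +
  ggplot2::labs(x = "normalized delay", y = "normalized lag / period")
```

For the excitatory Type I pair this reproduces the canonical progression:
bistable leader/follower modes at short delays (the follower's locking point
sits on the causal-limit branch, so the leader's spike directly evokes the
follower's), antiphase at intermediate delays, and a sharp transition to
tight $k = 2$ synchrony once the delay exceeds roughly 0.6 of the period and
the locking point reaches the low-noise causal-limit region of the PRC.

## Problem sizes and budgets

The default problem sizes — 2000 measurement samples per fit, an
$800\times800$ scan per feedback index, 5000 map cycles per histogram, 12
runs per bistability ensemble, and a 70-case (210-trajectory) random battery
for the solver-vs-map cross-validation — were chosen so the full test suite
and the reproduction script each run in minutes on a single core while
keeping every Monte-Carlo margin at four standard errors or better.

## Known limitations

* Exactly-zero-delay synchrony lies on the solver's grid boundary and is
  assessed via `assess_stability()` rather than returned by
  `find_lockings()`.
* The stability criterion is the two-point slope test; it does not cover
  relaxation oscillations with strong amplitude resetting, second-cycle
  resetting, or inputs strong enough to violate the one-input-per-cycle
  structure (period collapse aborts the map with a diagnostic instead).
* `heterogeneity_lag()` linearizes about the homogeneous locking point and
  degrades as $\varepsilon + \Delta\delta/2$ leaves the linear neighborhood
  (a few percent of the period for the templates here).
* The noisy map treats resetting draws as independent across arrivals;
  slowly varying excitability would correlate them and broaden histogram
  peaks relative to the model.
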