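# prcsync

Phase-resetting-curve (PRC) analysis of synchronization between two
reciprocally pulse-coupled neuronal oscillators with axonal conduction
delays.

## The problem

Rhythmically firing neurons — for instance entorhinal stellate cells pacing
the theta rhythm — often have to synchronize across distances that impose
conduction delays of a substantial fraction of the firing period. Whether a
given delay supports stable zero-lag synchrony, antiphase firing, or
bistable leader/follower locking is determined by a single measurable
object: the phase resetting curve

    f(phi) = (P_perturbed - P_intrinsic) / P_intrinsic,

the normalized change in cycle length caused by one synaptic input delivered
at phase `phi` of the cycle (positive = delay of the next spike, negative =
advance). Causality bounds every PRC by `f(phi) >= phi - 1`; on that causal
limit an excitatory input fires the cell immediately and the PRC is linear
with slope one.

For a 1:1 locking in which each neuron receives its partner's pulse at phase
`phi_i`, the stimulus and recovery intervals `ts_i = P_i phi_i`,
`tr_i = P_i (1 - phi_i + f_i(phi_i))` must close the delayed feedback loop
on the k-th subsequent spike:

    delta_12 + delta_21 + tr_i = ts_j + (k - 1) P_N,   for both (i, j),

and the locking is stable when the PRC slopes `s_i = f_i'(phi_i)` satisfy
`|(1 - s1)(1 - s2)| < |(1 + (k-1) s1)(1 + (k-1) s2)|` (synchronous modes
additionally need `|1 - (s1 + s2)| < 1`). The package implements this
apparatus end to end:

* `fit_prc()`, `classify_prc()` — binned polynomial PRC fitting with
  phase-dependent noise envelopes and Type I/II classification;
* `make_template()`, `generate_measurements()` — canonical excitatory and
  inhibitory Type I/II PRC shapes and synthetic dynamic-clamp-style
  measurement sets;
* `find_lockings()`, `assess_stability()`, `delay_sweep()` — all 1:1 locked
  modes of a delayed two-cell circuit with stability, mode class and
  normalized lags;
* `heterogeneity_lag()` — the linearized near-synchronous time lag under
  small period/delay differences, exact in its two limiting cases;
* `run_map()`, `run_map_ensemble()`, `lag_histogram()`,
  `circular_summary()` — a noisy event-driven iterated map, signed lag
  histograms, and circular statistics (mean network phase, locking
  strength R^2).

A thin command-line wrapper over the pipeline functions lives at
`inst/cli/prcsync.R` (subcommands `fit`, `sweep`, `simulate`, `make-data`).

## Worked example

Two identical 100 ms neurons with excitatory Type I PRCs, swept over
conduction delay:

```r
library(prcsync)
circ <- make_circuit(make_template("exc_I", noise = FALSE), period_a = 1)
find_lockings(circ, delay = 0.80)
#> # A tibble: 2 x 13
#>       k  phi1  phi2   ts1     tr1   ts2     tr2   tl1   tl2 period stable
#>   <int> <dbl> <dbl> <dbl>   <dbl> <dbl>   <dbl> <dbl> <dbl>  <dbl> <lgl>
#> 1     2 0.8   0.8   0.8   0.00800 0.8   0.00800 0     0.808  0.808 TRUE
#> 2     3 0.448 0.448 0.448 0.255   0.448 0.255   0.352 0.352  0.703 FALSE
#> # with 2 more variables: mode_class <chr> ("synchrony", "antiphase"), flags <chr>
```

At a normalized delay of 0.80 the only stable locking is `k = 2` synchrony
with one zero lag: each neuron receives its input at phase 0.8, where the
Type I PRC's slope is strongly positive, and the network period shrinks to
0.808 because both cells are advanced every cycle. At a delay of 0.04 the
same call returns two stable unequal-lag modes (bistable leader/follower)
and an unstable antiphase mode; at 0.40, stable antiphase with both lags at
half the network period.

The noisy map ties this to what a hybrid circuit actually shows:

```r
circ <- make_circuit(make_template("exc_II"), period_a = 100)
run <- run_map(circ, n_cycles = 5000, delay = 90, seed = 1)
circular_summary(run$lags)
#> <circular_summary> mean phase 0.0101, R^2 = 0.9708 (N = 5000)
```

A mean network phase of ~0 at locking strength R^2 ~ 0.97: tight synchrony,
because at a normalized delay of 0.9 the locking point sits in the
low-variance causal-limit region of the excitatory PRC. The same circuit at
delay 55 ms locks in antiphase (mean phase 0.50) with a much broader lag
distribution (R^2 ~ 0.69).

## Scientific notes

The methods vignette (`vignettes/prc-synchrony-methods.Rmd`) documents the
model and its assumptions, every numerical choice (binning and degree
selection, the stability criterion and its causal-limit and
endpoint-discontinuity overrides, map tie-breaks, histogram conventions),
how the synthetic templates were pinned down, and what the synthetic data do
and do not emulate.
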