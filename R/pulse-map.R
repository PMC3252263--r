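# Event-driven iterated map of two pulse-coupled oscillators with conduction
# delays, optionally driven by the PRC's measured noise.
#
# Between events each neuron's phase grows linearly at rate 1/P_j. Two event
# classes exist: spikes (phase reaches 1; phase resets to 0 and a pulse is
# queued for delivery to the partner after the conduction delay) and arrivals
# (a queued pulse reaches its target; the resetting f(phi) - noisy or mean -
# is subtracted from the target's phase). An arrival that lands exactly on
# the causal limit pushes the phase to 1 and the neuron fires immediately at
# the arrival time.

#' Simulate the noisy iterated pulse-coupled map
#'
#' @param spec a [make_circuit()] specification.
#' @param n_cycles number of neuron-1 cycles to keep after burn-in.
#' @param delay optional mean conduction delay (ms) overriding `spec`.
#' @param noise draw each resetting from the PRC's Gaussian noise model
#'   (`TRUE`) or use the mean curve (`FALSE`).
#' @param seed optional integer seed (drives both the initial phases when
#'   `phi_init` is NULL and the resetting noise).
#' @param phi_init length-2 initial phases in `[0, 1)`; drawn uniformly when
#'   NULL.
#' @param burn_in cycles discarded from the front before lag bookkeeping.
#' @param simultaneous tie-break for an arrival coinciding exactly with a
#'   spike of its target: `"after"` (default) processes the spike first so
#'   the input acts at phase 0 of the new cycle; `"before"` applies the input
#'   at the old phase just below 1.
#' @param max_events abort guard against period collapse (runaway event
#'   rate).
#' @return object of class `map_run`: list with `spikes` (list of two
#'   numeric vectors of spike times, ms), `lags` (a `lag_series`, see
#'   [lag_series()]), and `diagnostics` (counts of doublet cycles, negative-
#'   phase arrivals and total events).
#' @export
#' @examples
#' circ <- make_circuit(make_template("exc_I"), period_a = 1)
#' run <- run_map(circ, n_cycles = 200, delay = 0.8, seed = 1)
#' head(run$lags$lags)
run_map <- function(spec, n_cycles = 5000L, delay = NULL, noise = TRUE,
                    seed = NULL, phi_init = NULL, burn_in = 200L,
                    simultaneous = c("after", "before"),
                    max_events = NULL) {
  stopifnot(inherits(spec, "circuit_spec"), n_cycles >= 1L)
  simultaneous <- match.arg(simultaneous)
  spec <- override_delay(spec, delay)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phi_init)) phi_init <- stats::runif(2)
  stopifnot(length(phi_init) == 2L, all(phi_init >= 0), all(phi_init < 1))

  P <- c(spec$P1, spec$P2)
  tau <- c(spec$delay_12, spec$delay_21)  # tau[i]: delay from i to partner
  total_cycles <- n_cycles + burn_in
  if (is.null(max_events)) max_events <- 100L * total_cycles
  eps <- 1e-9 * max(P)

  # resetting evaluators bound to plain vectors for speed in the event loop
  mean_c <- list(spec$prc1$mean_coeffs, spec$prc2$mean_coeffs)
  up_c <- list(spec$prc1$sigma_upper_coeffs, spec$prc2$sigma_upper_coeffs)
  lo_c <- list(spec$prc1$sigma_lower_coeffs, spec$prc2$sigma_lower_coeffs)
  resetting_at <- function(j, phi) {
    m <- max(poly_eval(mean_c[[j]], phi), phi - 1)
    if (!noise) return(m)
    s <- max((poly_eval(up_c[[j]], phi) - poly_eval(lo_c[[j]], phi)) / 2, 0)
    if (s == 0) return(m)
    for (dr in seq_len(1000L)) {
      x <- stats::rnorm(1L, m, s)
      if (x >= phi - 1) return(x)
    }
    stop("rejection sampling exceeded 1000 draws in the map", call. = FALSE)
  }

  phi <- phi_init
  t_now <- 0
  # pending arrival times per direction (emitter 1 -> 2 and 2 -> 1); FIFO,
  # appended in emission order so always sorted
  q12 <- numeric(0)
  q21 <- numeric(0)
  spikes <- list(numeric(2 * total_cycles + 16L),
                 numeric(2 * total_cycles + 16L))
  n_spk <- c(0L, 0L)
  n_events <- 0L
  n_negphase <- 0L

  append_spike <- function(j, tm) {
    n_spk[j] <<- n_spk[j] + 1L
    if (n_spk[j] > length(spikes[[j]])) {
      spikes[[j]] <<- c(spikes[[j]], numeric(length(spikes[[j]])))
    }
    spikes[[j]][n_spk[j]] <<- tm
  }

  while (min(n_spk) < total_cycles + 1L) {
    n_events <- n_events + 1L
    if (n_events > max_events) {
      stop("event budget exceeded (", max_events,
           "): period collapse or runaway resetting", call. = FALSE)
    }
    t_spike <- t_now + (1 - phi) * P
    t_arr <- c(if (length(q21)) q21[1L] else Inf,  # arrival AT neuron 1
               if (length(q12)) q12[1L] else Inf)  # arrival AT neuron 2
    t_next_spike <- min(t_spike)
    t_next_arr <- min(t_arr)

    spike_first <- if (simultaneous == "after") {
      t_next_spike <= t_next_arr + eps
    } else {
      t_next_spike < t_next_arr - eps
    }

    if (spike_first) {
      j <- which.min(t_spike)
      te <- t_spike[j]
      phi <- pmin(phi + (te - t_now) / P, c(1, 1))
      t_now <- te
      append_spike(j, te)
      phi[j] <- 0
      if (j == 1L) q12 <- c(q12, te + tau[1L]) else q21 <- c(q21, te + tau[2L])
    } else {
      j <- which.min(t_arr)  # target neuron
      te <- t_arr[j]
      phi <- phi + (te - t_now) / P
      t_now <- te
      if (j == 1L) q21 <- q21[-1L] else q12 <- q12[-1L]
      ph <- phi[j]
      if (ph < 0) { n_negphase <- n_negphase + 1L; ph <- 0 }
      ph <- min(ph, 1 - 1e-12)
      phi[j] <- phi[j] - resetting_at(j, ph)
      # causal-limit arrivals (phi - f = 1) fire on the next loop pass at te
    }
  }

  spikes <- list(spikes[[1L]][seq_len(n_spk[1L])],
                 spikes[[2L]][seq_len(n_spk[2L])])
  lags <- lag_series(spikes, spec, burn_in = burn_in)
  structure(
    list(
      spikes = spikes,
      lags = lags,
      diagnostics = list(
        n_events = n_events,
        n_negative_phase_arrivals = n_negphase,
        doublet_cycles = attr(lags, "doublet_cycles")
      )
    ),
    class = "map_run"
  )
}

#' @export
print.map_run <- function(x, ...) {
  cat(sprintf("<map_run> %d + %d spikes, %d lag cycles, %d doublets\n",
              length(x$spikes[[1]]), length(x$spikes[[2]]),
              nrow(x$lags$lags), x$diagnostics$doublet_cycles))
  invisible(x)
}

#' Pool noisy map runs from random initial conditions
#'
#' Runs the map `n_runs` times from independently drawn initial phases and
#' pools the per-cycle lags into one series. In a bistable regime single
#' trajectories settle into whichever basin they start in (the basin
#' boundaries lie several noise standard deviations from the locked states),
#' so sampling the full mode structure - e.g. the five-peak histogram of
#' noisy bistability between synchrony and antiphase - requires pooling
#' independent initial conditions.
#'
#' @inheritParams run_map
#' @param n_runs number of independent runs.
#' @param cycles_per_run cycles kept per run after burn-in.
#' @return a pooled [lag_series()].
#' @export
run_map_ensemble <- function(spec, n_runs = 12L, cycles_per_run = 400L,
                             delay = NULL, noise = TRUE, seed = NULL,
                             burn_in = 150L, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(i) {
    run_map(spec, n_cycles = cycles_per_run, delay = delay, noise = noise,
            seed = NULL, phi_init = NULL, burn_in = burn_in, ...)$lags$lags
  })
  lags <- do.call(rbind, runs)
  lags$cycle <- seq_len(nrow(lags))
  structure(
    list(lags = lags, p_slow = max(spec$P1, spec$P2),
         p_network = mean(lags$period)),
    class = "lag_series",
    doublet_cycles = NA_integer_
  )
}

#' Per-cycle time lags from two spike trains
#'
#' For each neuron-1 cycle (consecutive neuron-1 spikes), `tl1` is the
#' interval from the cycle's opening spike to the next neuron-2 spike,
#' wherever it falls, and `tl2` the interval from that neuron-2 spike to the
#' following neuron-1 spike. In a clean 1:1 alternation `tl1 + tl2` equals
#' the cycle period; when the locking is near-synchronous and the leader
#' switches, `tl1` hops between ~0 and ~one network period, producing the
#' characteristic wrap peaks of the lag histograms. Cycles whose lag exceeds
#' 1.5x the median period (the 1:1 pairing skipped a whole cycle - true
#' doublets) are excluded and counted.
#'
#' @param spikes list of two numeric vectors of spike times (ms).
#' @param spec the circuit the spikes came from (for the normalization
#'   period).
#' @param burn_in number of leading neuron-1 cycles to drop.
#' @return object of class `lag_series`: list with `lags` tibble (`cycle`,
#'   `tl1`, `tl2`, `period`), `p_slow`, `p_network`; attribute
#'   `doublet_cycles`.
#' @export
lag_series <- function(spikes, spec, burn_in = 0L) {
  s1 <- spikes[[1L]]; s2 <- spikes[[2L]]
  if (burn_in > 0L) {
    cutoff <- if (length(s1) > burn_in) s1[burn_in + 1L] else Inf
    s1 <- s1[s1 >= cutoff]
    s2 <- s2[s2 >= cutoff]
  }
  eps <- 1e-9 * max(spec$P1, spec$P2)
  n_cyc <- length(s1) - 1L
  empty <- tibble::tibble(cycle = integer(0), tl1 = numeric(0),
                          tl2 = numeric(0), period = numeric(0))
  if (n_cyc < 1L || length(s2) == 0L) {
    return(structure(
      list(lags = empty, p_slow = max(spec$P1, spec$P2),
           p_network = NA_real_),
      class = "lag_series", doublet_cycles = 0L))
  }
  heads <- s1[seq_len(n_cyc)]
  per <- diff(s1)
  # next neuron-2 spike at or after each cycle head (simultaneous counts)
  i2 <- findInterval(heads - eps, s2) + 1L
  ok <- i2 <= length(s2)
  t2 <- rep(NA_real_, n_cyc); t2[ok] <- s2[i2[ok]]
  tl1 <- t2 - heads
  # next neuron-1 spike at or after that neuron-2 spike
  i1 <- findInterval(t2 - eps, s1) + 1L
  ok <- ok & !is.na(t2) & i1 <= length(s1)
  tl2 <- rep(NA_real_, n_cyc)
  tl2[ok] <- s1[i1[ok]] - t2[ok]
  med_p <- stats::median(per)
  keep <- ok & !is.na(tl1) & tl1 <= 1.5 * med_p & tl2 <= 1.5 * med_p
  keep[is.na(keep)] <- FALSE
  doublets <- sum(ok & !keep)
  structure(
    list(
      lags = tibble::tibble(cycle = which(keep), tl1 = tl1[keep],
                            tl2 = tl2[keep], period = per[keep]),
      p_slow = max(spec$P1, spec$P2),
      p_network = if (any(keep)) mean(per[keep]) else NA_real_
    ),
    class = "lag_series",
    doublet_cycles = doublets
  )
}

#' @export
print.lag_series <- function(x, ...) {
  cat(sprintf("<lag_series> %d cycles, mean network period %.4g ms\n",
              nrow(x$lags), x$p_network))
  invisible(x)
}

#' Signed lag histogram
#'
#' Pools lag 1 as positive and lag 2 as negative, normalized by the mean
#' network period (so a synchronous mode shows peaks at 0 and +/-1 and an
#' antiphase mode two peaks near +/-0.5), and bins the result into a density.
#'
#' @param series a [lag_series()].
#' @param bins number of bins.
#' @param normalize `"network"` (mean network period, default) or `"slower"`
#'   (the slower neuron's intrinsic period).
#' @return tibble with `bin_center`, `count`, `density`; the density
#'   integrates to 1 over the binned range.
#' @export
lag_histogram <- function(series, bins = 42L, normalize = c("network",
                                                            "slower")) {
  stopifnot(inherits(series, "lag_series"))
  normalize <- match.arg(normalize)
  lg <- series$lags
  if (nrow(lg) < 100L) {
    stop("need at least 100 cycles for a lag histogram, got ", nrow(lg),
         call. = FALSE)
  }
  pn <- if (normalize == "network") series$p_network else series$p_slow
  v <- c(lg$tl1, -lg$tl2) / pn
  lim <- max(1.05, max(abs(v)) + 1e-9)
  breaks <- seq(-lim, lim, length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(
    bin_center = h$mids,
    count = h$counts,
    density = h$counts / sum(h$counts) / diff(breaks)[1L]
  )
}

#' Count peaks in a lag histogram
#'
#' A peak is a local maximum of the lightly smoothed counts exceeding a
#' fraction of the tallest bin. Property-style summary for comparing a noisy
#' run against the predicted mode structure: an antiphase mode gives 2 peaks,
#' homogeneous synchrony 3 (0 and both wrap images at +/- one network
#' period), noisy bistability 5; heterogeneity pins the leader and removes
#' one wrap peak.
#'
#' @param hist tibble from [lag_histogram()].
#' @param min_frac peak threshold as a fraction of the maximum smoothed
#'   count.
#' @return integer count; attribute `"locations"` has the peak bin centers.
#' @export
count_lag_peaks <- function(hist, min_frac = 0.05) {
  ct <- hist$count
  n <- length(ct)
  sm <- (c(0, ct[-n]) + 2 * ct + c(ct[-1L], 0)) / 4
  thr <- min_frac * max(sm)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    # strict rise from the left, non-rise to the right: counts plateaus once
    is_peak[i] <- sm[i] >= thr && sm[i] > left && sm[i] >= right
  }
  structure(sum(is_peak), locations = hist$bin_center[is_peak])
}
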