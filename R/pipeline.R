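# Pipeline drivers: file-in/file-out wrappers used by the command-line
# script in inst/cli/prcsync.R and by batch reproduction of the delay-sweep
# and histogram experiments.

#' Fit a PRC model from a sample CSV and write it as JSON
#'
#' @param prc_csv input CSV with columns `phase,resetting`.
#' @param out_json output model JSON path.
#' @param coupling_sign coupling sign of the measurements.
#' @param ... further arguments passed to [fit_prc()].
#' @return the fitted [prc_model()], invisibly.
#' @export
fit_prc_file <- function(prc_csv, out_json,
                         coupling_sign = c("excitatory", "inhibitory"),
                         ...) {
  samples <- read_prc_samples(prc_csv, coupling_sign = coupling_sign)
  model <- fit_prc(samples, ...)
  if (attr(model, "n_bins_merged") > 0L) {
    message(attr(model, "n_bins_merged"), " bins merged with neighbors")
  }
  if (!attr(model, "envelope_ok")) {
    message("fitted envelopes cross the mean somewhere on [0,1)")
  }
  write_prc_model(model, out_json)
  invisible(model)
}

#' Run a delay sweep from a circuit JSON and write the mode table as CSV
#'
#' @param circuit_json input circuit specification.
#' @param out_csv output CSV path.
#' @param delays_norm normalized delay grid.
#' @param heterogeneity optional fractional period difference overriding the
#'   circuit's, e.g. 0.04 for the detuned variants of the prediction
#'   figures.
#' @param ... further arguments passed to [delay_sweep()].
#' @return the sweep tibble, invisibly.
#' @export
run_sweep_file <- function(circuit_json, out_csv,
                           delays_norm = seq(0, 1, by = 0.02),
                           heterogeneity = NULL, ...) {
  spec <- read_circuit(circuit_json)
  if (!is.null(heterogeneity)) spec$P2 <- spec$P1 * (1 + heterogeneity)
  sw <- delay_sweep(spec, delays_norm = delays_norm, ...)
  out <- sw[, intersect(
    c("delay_norm", "k", "phi1", "phi2", "tl1_norm", "tl2_norm",
      "period_norm", "stable", "mode_class", "flags"), names(sw))]
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(sw)
}

#' Simulate a circuit at one delay and write spike/lag/histogram/summary
#' files
#'
#' Runs the noisy map, then writes `<prefix>_spikes.csv` (neuron,
#' spike_time_ms), `<prefix>_lags.csv` (cycle, tl1_ms, tl2_ms),
#' `<prefix>_hist.csv` (bin_center, density) and `<prefix>_summary.json`
#' (mean_phase, R2, N).
#'
#' @param circuit_json input circuit specification.
#' @param delay_norm delay normalized by the slower neuron's period.
#' @param out_prefix path prefix for the four output files.
#' @param n_cycles,seed,noise passed to [run_map()].
#' @param n_runs 1 for a single trajectory; larger values pool runs from
#'   random initial conditions via [run_map_ensemble()] (for bistable
#'   regimes), splitting `n_cycles` across runs.
#' @param ... further arguments passed to [run_map()].
#' @return list with the `map_run` (NULL when pooling), the pooled
#'   `lag_series`, histogram and `circular_summary`, invisibly.
#' @export
simulate_circuit_file <- function(circuit_json, delay_norm, out_prefix,
                                  n_cycles = 5000L, seed = NULL,
                                  noise = TRUE, n_runs = 1L, ...) {
  spec <- read_circuit(circuit_json)
  p_slow <- max(spec$P1, spec$P2)
  if (n_runs > 1L) {
    run <- NULL
    lags <- run_map_ensemble(spec, n_runs = n_runs,
                             cycles_per_run = ceiling(n_cycles / n_runs),
                             delay = delay_norm * p_slow, noise = noise,
                             seed = seed, ...)
    spikes <- list(numeric(0), numeric(0))
  } else {
    run <- run_map(spec, n_cycles = n_cycles, delay = delay_norm * p_slow,
                   noise = noise, seed = seed, ...)
    lags <- run$lags
    spikes <- run$spikes
  }
  hist <- lag_histogram(lags)
  summ <- circular_summary(lags)

  utils::write.csv(
    data.frame(
      neuron = rep(1:2, times = lengths(spikes)),
      spike_time_ms = c(spikes[[1]], spikes[[2]])
    ),
    paste0(out_prefix, "_spikes.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(cycle = lags$lags$cycle, tl1_ms = lags$lags$tl1,
               tl2_ms = lags$lags$tl2),
    paste0(out_prefix, "_lags.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(bin_center = hist$bin_center, density = hist$density),
    paste0(out_prefix, "_hist.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean_phase = summ$mean_phase, R2 = summ$R2, N = summ$N),
    paste0(out_prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(run = run, lags = lags, hist = hist, summary = summ))
}

#' Generate template-based synthetic data files
#'
#' Writes a PRC sample CSV and the generating model JSON for a named
#' template.
#'
#' @param template template name, see [make_template()].
#' @param out_csv,out_json output paths.
#' @param n_samples,seed passed to [generate_measurements()].
#' @param scale template amplitude.
#' @return the generated [prc_measurements()], invisibly.
#' @export
make_data_files <- function(template, out_csv, out_json,
                            n_samples = 2000L, seed = NULL, scale = 0.3) {
  model <- make_template(template, scale = scale)
  samples <- generate_measurements(model, n_samples = n_samples, seed = seed)
  write_prc_samples(samples, out_csv)
  write_prc_model(model, out_json)
  invisible(samples)
}
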