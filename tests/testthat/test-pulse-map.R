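test_that("uncoupled oscillators keep their intrinsic period and initial offset", {
  circ <- zero_prc_circuit(period = 1, delay = 0.3)
  run <- run_map(circ, n_cycles = 50, noise = FALSE, phi_init = c(0.3, 0.55),
                 burn_in = 0)
  isi1 <- diff(run$spikes[[1]])
  isi2 <- diff(run$spikes[[2]])
  expect_true(all(abs(isi1 - 1) < 1e-9))
  expect_true(all(abs(isi2 - 1) < 1e-9))
  # neuron 2 started 0.25 cycle closer to threshold: constant lags
  expect_true(all(abs(run$lags$lags$tl1 - 0.75) < 1e-9))
})

test_that("event ordering matches an independent naive event-scan reference", {
  cases <- list(
    list(spec = unit_circuit("exc_I", noise = FALSE, delay = 0.3),
         phi = c(0.15, 0.6)),
    list(spec = unit_circuit("inh_II", noise = FALSE, heterogeneity = 0.04,
                             delay = 0.19), phi = c(0.4, 0.1)),
    list(spec = unit_circuit("exc_II", noise = FALSE, delay = 0.85),
         phi = c(0.05, 0.0))
  )
  for (cs in cases) {
    run <- run_map(cs$spec, n_cycles = 40, noise = FALSE, phi_init = cs$phi,
                   burn_in = 0)
    ref <- naive_map_ref(cs$spec, n_spikes_each = 35, phi_init = cs$phi)
    for (j in 1:2) {
      n <- length(ref[[j]])
      expect_equal(run$spikes[[j]][seq_len(n)], ref[[j]], tolerance = 1e-9)
    }
  }
})

test_that("runs are reproducible under a seed and differ across seeds", {
  circ <- unit_circuit("exc_II", delay = 0.55)
  a <- run_map(circ, n_cycles = 100, seed = 5)
  b <- run_map(circ, n_cycles = 100, seed = 5)
  c <- run_map(circ, n_cycles = 100, seed = 6)
  expect_identical(a$spikes, b$spikes)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("zero-noise trajectories converge to solver-stable lockings", {
  circ <- unit_circuit("exc_I", noise = FALSE)
  # near-causal-limit synchrony at a long delay (k = 2)
  run <- run_map(circ, n_cycles = 300, delay = 0.8, noise = FALSE,
                 phi_init = c(0.82, 0.80), burn_in = 250)
  expect_lt(abs(tail_lag(run)), 0.005)
  # antiphase at an intermediate delay
  run2 <- run_map(circ, n_cycles = 300, delay = 0.4, noise = FALSE,
                  phi_init = c(0.5, 0.1), burn_in = 250)
  lg <- utils::tail(run2$lags$lags, 30)
  expect_lt(max(abs(lg$tl1 / lg$period - 0.5)), 0.01)
})

test_that("an arrival on the causal limit evokes an immediate spike", {
  # constant polynomial far below the limit: every input is clamped, so the
  # follower fires at the moment the pulse arrives
  m <- prc_model(-2, coupling_sign = "excitatory")
  circ <- make_circuit(m, period_a = 1, delay = 0.4)
  run <- run_map(circ, n_cycles = 20, noise = FALSE, phi_init = c(0.5, 0),
                 burn_in = 5)
  # neuron 2 fires exactly delay after each neuron-1 spike (leader/follower
  # at the causal limit)
  lg <- utils::tail(run$lags$lags, 10)
  expect_true(all(abs(pmin(lg$tl1, lg$tl2) - 0.4) < 1e-9))
})

test_that("lag histograms integrate to one and find the right peaks", {
  # constant antiphase lags: delta peaks at +/- 0.5
  lags <- tibble::tibble(cycle = 1:200, tl1 = rep(0.5, 200),
                         tl2 = rep(0.5, 200), period = rep(1, 200))
  ser <- structure(list(lags = lags, p_slow = 1, p_network = 1),
                   class = "lag_series")
  h <- lag_histogram(ser, bins = 42)
  width <- diff(h$bin_center[1:2])
  expect_equal(sum(h$density) * width, 1, tolerance = 1e-12)
  pk <- count_lag_peaks(h)
  expect_identical(as.integer(pk), 2L)
  # the delta values sit on bin edges; centers land within one bin width
  expect_lt(max(abs(abs(attr(pk, "locations")) - 0.5)), 0.03)

  # histogram is invariant under cycle reordering
  shuffled <- ser
  shuffled$lags <- shuffled$lags[sample.int(200), ]
  expect_equal(lag_histogram(shuffled, bins = 42), h)

  # too few cycles is an error
  short <- ser; short$lags <- short$lags[1:50, ]
  expect_error(lag_histogram(short), "at least 100")
})

test_that("ensemble pooling samples both basins of a bistable circuit", {
  circ <- unit_circuit("inh_II", noise = FALSE, period = 100)
  ens <- run_map_ensemble(circ, n_runs = 8, cycles_per_run = 200,
                          delay = 19, noise = FALSE, seed = 3, burn_in = 150)
  lag_norm <- pmin(ens$lags$tl1, ens$lags$tl2) / ens$lags$period
  expect_gt(sum(lag_norm < 0.05), 0)  # some runs locked in synchrony
  expect_gt(sum(abs(lag_norm - 0.5) < 0.05), 0)  # others in antiphase
})

test_that("period collapse is caught by the event budget", {
  circ <- unit_circuit("exc_I", noise = FALSE, delay = 0.3)
  expect_error(run_map(circ, n_cycles = 100, noise = FALSE,
                       max_events = 20), "event budget")
})
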