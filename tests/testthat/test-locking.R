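test_that("an uncoupled pair (zero resetting) is flagged degenerate", {
  circ <- zero_prc_circuit()
  modes <- find_lockings(circ, delay = 0, k_max = 1)
  expect_true(attr(modes, "degenerate"))
  modes2 <- find_lockings(circ, delay = 0.2, k_max = 1)
  expect_true(attr(modes2, "degenerate"))
})

test_that("found modes satisfy both periodicity residuals (brute-force check)", {
  circ <- unit_circuit("exc_I", noise = FALSE)
  for (d in c(0.04, 0.3, 0.55, 0.8)) {
    modes <- find_lockings(circ, delay = d)
    for (i in seq_len(nrow(modes))) {
      k <- modes$k[i]
      D <- 2 * d
      u1 <- modes$ts1[i] + (k - 1) * modes$period[i]
      u2 <- modes$ts2[i] + (k - 1) * modes$period[i]
      expect_lt(abs(u1 - D - modes$tr2[i]), 1e-9)
      expect_lt(abs(D + modes$tr1[i] - u2), 1e-9)
    }
  }
})

test_that("every sign change of a dense residual scan is matched by a found mode", {
  circ <- unit_circuit("exc_II", noise = FALSE)
  d <- 0.3
  modes <- find_lockings(circ, delay = d, k_max = 2)
  # independent scan along the symmetric diagonal (identical neurons):
  # residual of the k = 1 and k = 2 constraints at phi1 = phi2 = phi
  phi <- seq(1e-6, 1 - 1e-6, length.out = 4000)
  f <- evaluate_prc(circ$prc1, phi)
  tr <- 1 - phi + f
  for (k in 1:2) {
    res <- 2 * d + tr - phi - (k - 1) * (phi + tr)
    flips <- which(diff(sign(res)) != 0)
    for (ix in flips) {
      root <- phi[ix]
      dist <- abs(modes$phi1[modes$k == k] - root)
      expect_lt(min(c(dist, Inf)), 2e-3)
    }
  }
})

test_that("interval-curve intersections line up with the solver's modes", {
  circ <- unit_circuit("exc_I", noise = FALSE)
  cur <- interval_curves(circ, delay = 0.04, k = 1, n = 2001)
  modes <- find_lockings(circ, delay = 0.04)
  m1 <- modes[modes$k == 1, ]
  for (i in seq_len(nrow(m1))) {
    # neuron 1's curve point at phi1 must coincide with neuron 2's at phi2
    x <- 2 * 0.04 + m1$tr1[i]   # shared abscissa: D + tr1 = ts2 (k = 1)
    y <- m1$ts1[i]              # shared ordinate: ts1 = D + tr2
    j <- which.min(abs(cur$neuron2$phi - m1$phi2[i]))
    expect_lt(abs(cur$neuron2$x[j] - x), 2e-3)
    expect_lt(abs(cur$neuron2$y[j] - y), 2e-3)
  }
})

test_that("network period is conserved and equals the lag sum", {
  for (nm in c("exc_I", "exc_II", "inh_I", "inh_II")) {
    circ <- unit_circuit(nm, noise = FALSE)
    for (d in c(0.1, 0.4, 0.7)) {
      modes <- find_lockings(circ, delay = d)
      for (i in seq_len(nrow(modes))) {
        pn1 <- modes$ts1[i] + modes$tr1[i]
        pn2 <- modes$ts2[i] + modes$tr2[i]
        expect_lt(abs(pn1 - pn2), 1e-9 * pn1)
        expect_lt(abs(modes$tl1[i] + modes$tl2[i] - pn1), 1e-9 * pn1)
      }
    }
  }
})

test_that("identical neurons with equal delays give lag-swapped mode pairs", {
  circ <- unit_circuit("exc_I", noise = FALSE)
  modes <- find_lockings(circ, delay = 0.04)
  m1 <- modes[modes$k == 1, ]
  for (i in seq_len(nrow(m1))) {
    partner <- vapply(seq_len(nrow(m1)), function(j) {
      abs(m1$tl1[j] - m1$tl2[i]) < 1e-6 && abs(m1$tl2[j] - m1$tl1[i]) < 1e-6
    }, logical(1))
    expect_true(any(partner))
  }
})

test_that("the slope criterion arithmetic matches its analytic special cases", {
  lin <- function(s) prc_model(c(0.05, s), coupling_sign = "excitatory")
  mk_mode <- function(period = 1.05) {
    tibble::tibble(k = 2L, phi1 = 0.3, phi2 = 0.3, tl1 = 0, tl2 = period,
                   period = period)
  }
  # sum of slopes 0.5: |1 - 0.5| < 1 -> stable synchrony
  circ <- make_circuit(lin(0.25), lin(0.25), period_a = 1)
  expect_true(assess_stability(mk_mode(), circ))
  # sum of slopes 2.5: |1 - 2.5| = 1.5 -> unstable (large slopes destabilize)
  circ2 <- make_circuit(lin(1.25), lin(1.25), period_a = 1)
  expect_false(assess_stability(mk_mode(), circ2))
})

test_that("the endpoint discontinuity destabilizes zero-delay inhibitory synchrony only", {
  circ <- unit_circuit("inh_I", noise = FALSE)
  sync0 <- tibble::tibble(k = 1L, phi1 = 0, phi2 = 0, tl1 = 0, tl2 = 1,
                          period = 1)
  verdict <- assess_stability(sync0, circ)
  expect_false(as.logical(verdict))
  expect_match(attr(verdict, "flags"), "discontinuity")

  # a short delay moves the locking point off the discontinuity
  modes <- find_lockings(circ, delay = 0.05)
  sync <- modes[modes$mode_class == "synchrony", ]
  expect_true(all(sync$stable))
  expect_false(any(grepl("discontinuity", sync$flags)))
})

test_that("heterogeneity lag: exact limits and map cross-validation", {
  # identical neurons, equal delays (stable locking point): exactly zero
  circ <- unit_circuit("exc_I", noise = FALSE, period = 100, delay = 70)
  expect_identical(heterogeneity_lag(circ), 0)

  # both locking points on the causal limit: exactly ddelta/2
  cc <- unit_circuit("exc_I", noise = FALSE, period = 100, delay = 90,
                     delta_delay = 2)
  expect_identical(heterogeneity_lag(cc), 1)

  # unstable homogeneous locking point: refuse
  cu <- unit_circuit("exc_I", noise = FALSE, period = 100, delay = 30)
  expect_error(heterogeneity_lag(cu), "not stable")

  # linearized lag matches the zero-noise map off the causal limit
  het <- make_circuit(make_template("inh_II", noise = FALSE),
                      period_a = 100, heterogeneity = 0.04)
  for (dn in c(0.19, 0.31)) {
    spec_d <- make_circuit(make_template("inh_II", noise = FALSE),
                           period_a = 100, heterogeneity = 0.04,
                           delay = dn * het$P2)
    eps_lin <- heterogeneity_lag(spec_d)
    run <- run_map(spec_d, 500, noise = FALSE, phi_init = c(0.03, 0),
                   burn_in = 400)
    eps_map <- tail_lag(run)
    expect_lt(abs(eps_lin - eps_map), 0.15 * abs(eps_map) + 0.2)
  }

  # on the causal limit the synchronous mode shrugs off period differences
  for (h in c(0.01, 0.02, 0.04)) {
    chet <- make_circuit(make_template("exc_II", noise = FALSE),
                         period_a = 100, heterogeneity = h, delay = 85)
    expect_identical(heterogeneity_lag(chet), 0)
  }
})

test_that("delay sweeps reproduce the progression of stable firing patterns", {
  circ <- unit_circuit("exc_I", noise = FALSE)
  sw <- delay_sweep(circ, delays_norm = c(0.04, 0.4, 0.8),
                    stable_only = TRUE)
  cls <- function(d) sort(unique(sw$mode_class[sw$delay_norm == d]))
  expect_identical(cls(0.04), "leader_follower")
  expect_identical(cls(0.4), "antiphase")
  expect_identical(cls(0.8), "synchrony")
  # normalized columns and signed lags are consistent
  expect_equal(sw$tl1_signed, sw$tl1_norm)
  expect_equal(sw$tl2_signed, -sw$tl2_norm)
  expect_equal(sw$tl1_norm + sw$tl2_norm, sw$period_norm, tolerance = 1e-9)
})

test_that("inhibitory bistability window appears in a sweep of the Type II pair", {
  circ <- unit_circuit("inh_II", noise = FALSE)
  sw <- delay_sweep(circ, delays_norm = c(0.09, 0.19, 0.31),
                    stable_only = TRUE)
  at <- function(d, cls) any(sw$delay_norm == d & sw$mode_class == cls)
  expect_true(at(0.09, "antiphase") && !at(0.09, "synchrony"))
  expect_true(at(0.19, "antiphase") && at(0.19, "synchrony"))
  expect_true(at(0.31, "synchrony") && !at(0.31, "antiphase"))
})
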