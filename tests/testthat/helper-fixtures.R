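# Shared fixtures and an independent reference implementation of the
# event-driven map used to cross-check event ordering.

unit_circuit <- function(name, heterogeneity = 0, noise = TRUE,
                         period = 1, delay = 0, delta_delay = 0) {
  make_circuit(make_template(name, noise = noise), period_a = period,
               heterogeneity = heterogeneity, delay = delay,
               delta_delay = delta_delay)
}

zero_prc_circuit <- function(period = 1, delay = 0) {
  m <- prc_model(0, coupling_sign = "excitatory")
  make_circuit(m, period_a = period, delay = delay)
}

# Naive event-scan reference map (zero noise): every pending pulse is kept in
# a flat data.frame and the global next event is found by rescanning all
# candidates each step. Independent of the package's queue bookkeeping; ties
# resolved the same way (spike first, neuron 1 before neuron 2).
naive_map_ref <- function(spec, n_spikes_each, phi_init) {
  P <- c(spec$P1, spec$P2)
  tau12 <- spec$delay_12; tau21 <- spec$delay_21
  phi <- phi_init
  t_now <- 0
  pulses <- data.frame(target = integer(0), arrival = numeric(0))
  spk <- list(numeric(0), numeric(0))
  guard <- 0L
  while (min(lengths(spk)) < n_spikes_each) {
    guard <- guard + 1L
    if (guard > 100L * n_spikes_each) stop("reference map runaway")
    cand_t <- c(t_now + (1 - phi[1]) * P[1], t_now + (1 - phi[2]) * P[2],
                pulses$arrival)
    cand_kind <- c("spike", "spike", rep("arrival", nrow(pulses)))
    cand_who <- c(1L, 2L, pulses$target)
    # spikes win ties, then lower neuron index
    ord <- order(cand_t, cand_kind == "arrival", cand_who)
    pick <- ord[1]
    te <- cand_t[pick]
    phi <- phi + (te - t_now) / P
    t_now <- te
    if (cand_kind[pick] == "spike") {
      j <- cand_who[pick]
      spk[[j]] <- c(spk[[j]], te)
      phi[j] <- 0
      pulses <- rbind(pulses, data.frame(
        target = 3L - j,
        arrival = te + if (j == 1L) tau12 else tau21))
    } else {
      j <- cand_who[pick]
      row <- which(pulses$target == j & pulses$arrival == te)[1]
      pulses <- pulses[-row, , drop = FALSE]
      ph <- min(max(phi[j], 0), 1 - 1e-12)
      prc <- if (j == 1L) spec$prc1 else spec$prc2
      phi[j] <- phi[j] - evaluate_prc(prc, ph)
    }
  }
  spk
}

# Mean lag over the tail of a zero-noise run, wrapped to (-P/2, P/2]
tail_lag <- function(run, n_tail = 50) {
  lg <- utils::tail(run$lags$lags, n_tail)
  eps <- ifelse(lg$tl1 <= lg$period / 2, lg$tl1, lg$tl1 - lg$period)
  mean(eps)
}
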