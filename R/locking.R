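# Existence and stability of 1:1 phase-locked modes of a delayed two-neuron
# circuit.
#
# For a 1:1 locking, each neuron i receives its partner's input at a fixed
# phase phi_i of its own cycle. With stimulus interval ts_i = P_i*phi_i and
# recovery interval tr_i = P_i*(1 - phi_i + f_i(phi_i)), the loop through
# both conduction delays closes on the k-th subsequent spike of the emitting
# neuron, imposing two periodicity constraints:
#
#   D + tr_1(phi_1) = ts_2(phi_2) + (k-1) * P_N2(phi_2)
#   D + tr_2(phi_2) = ts_1(phi_1) + (k-1) * P_N1(phi_1)
#
# where D = delay_12 + delay_21 and P_Ni = ts_i + tr_i. Adding the two
# constraints shows that any simultaneous solution automatically equalizes
# the two network periods. Solutions are intersections of one interval curve
# per neuron, with abscissa and ordinate reversed for one of them.

ts_fun <- function(P, phi) P * phi
tr_fun <- function(P, prc, phi) P * (1 - phi + evaluate_prc(prc, phi))

#' Interval curves of the graphical locking method
#'
#' For each neuron, the stimulus and recovery intervals are functions of the
#' phase at which the input is received. Plotting, for neuron 1,
#' `x = D + tr_1` against `y = ts_1 + (k-1)*P_N1` and, for neuron 2 with the
#' axes reversed, `x = ts_2 + (k-1)*P_N2` against `y = D + tr_2`, both
#' periodicity constraints of a 1:1 locking hold exactly where the two curves
#' intersect.
#'
#' @param spec a [make_circuit()] specification.
#' @param delay optional mean conduction delay (ms) overriding the one in
#'   `spec` (the delay difference is preserved).
#' @param k feedback cycle index (`>= 1`): the number of cycles for a spike's
#'   effect to return to the emitting neuron through the loop.
#' @param n number of grid phases.
#' @return list of two tibbles (`neuron1`, `neuron2`) with columns `phi`,
#'   `x`, `y` (ms).
#' @export
interval_curves <- function(spec, delay = NULL, k = 1L, n = 512L) {
  stopifnot(inherits(spec, "circuit_spec"), k >= 1L)
  spec <- override_delay(spec, delay)
  D <- spec$delay_12 + spec$delay_21
  phi <- seq(1e-9, 1 - 1e-9, length.out = n)
  ts1 <- ts_fun(spec$P1, phi); tr1 <- tr_fun(spec$P1, spec$prc1, phi)
  ts2 <- ts_fun(spec$P2, phi); tr2 <- tr_fun(spec$P2, spec$prc2, phi)
  list(
    neuron1 = tibble::tibble(phi = phi, x = D + tr1,
                             y = ts1 + (k - 1) * (ts1 + tr1)),
    neuron2 = tibble::tibble(phi = phi, x = ts2 + (k - 1) * (ts2 + tr2),
                             y = D + tr2)
  )
}

override_delay <- function(spec, delay) {
  if (is.null(delay)) return(spec)
  stopifnot(delay >= 0)
  dd <- spec$delay_12 - spec$delay_21
  spec$delay_12 <- delay + dd / 2
  spec$delay_21 <- delay - dd / 2
  if (spec$delay_12 < 0 || spec$delay_21 < 0) {
    stop("delay override makes a directional delay negative", call. = FALSE)
  }
  spec
}

# Solve the two periodicity residuals for one k by a sign-change scan of the
# separable residuals on an n x n grid, refined by damped Newton iterations
# with the analytic Jacobian. Returns a list of (phi1, phi2) pairs plus a
# degeneracy flag (residual zero along a curve rather than at points, e.g.
# two uncoupled identical cells).
solve_k <- function(spec, k, grid_n = 800L, tol_factor = 1e-10) {
  D <- spec$delay_12 + spec$delay_21
  P1 <- spec$P1; P2 <- spec$P2
  p_slow <- max(P1, P2)
  tol <- tol_factor * p_slow

  phi <- seq(1e-9, 1 - 1e-9, length.out = grid_n)
  f1 <- evaluate_prc(spec$prc1, phi); f2 <- evaluate_prc(spec$prc2, phi)
  tr1 <- P1 * (1 - phi + f1);         tr2 <- P2 * (1 - phi + f2)
  u1 <- P1 * phi + (k - 1) * (P1 * phi + tr1)
  u2 <- P2 * phi + (k - 1) * (P2 * phi + tr2)

  # residuals: G1(i,j) = u1[i] - (D + tr2[j]); G2(i,j) = (D + tr1[i]) - u2[j]
  a1 <- u1;      b1 <- D + tr2   # G1 = a1[i] - b1[j]
  a2 <- D + tr1; b2 <- u2        # G2 = a2[i] - b2[j]

  cells <- candidate_cells(a1, b1, a2, b2)
  if (nrow(cells) == 0L) {
    return(list(solutions = list(), degenerate = FALSE))
  }
  # A residual vanishing along a whole curve (uncoupled degenerate circuit)
  # floods the scan with candidate cells; treat as degenerate, not as modes.
  degenerate <- nrow(cells) > grid_n

  g_fun <- function(x) {
    fe1 <- evaluate_prc(spec$prc1, x[1]); fe2 <- evaluate_prc(spec$prc2, x[2])
    trr1 <- P1 * (1 - x[1] + fe1);        trr2 <- P2 * (1 - x[2] + fe2)
    uu1 <- P1 * x[1] + (k - 1) * (P1 * x[1] + trr1)
    uu2 <- P2 * x[2] + (k - 1) * (P2 * x[2] + trr2)
    c(uu1 - D - trr2, D + trr1 - uu2)
  }
  jac_fun <- function(x) {
    s1 <- prc_slope(spec$prc1, x[1]); s2 <- prc_slope(spec$prc2, x[2])
    # u_i = P_i*phi + (k-1)*P_i*(1 + f_i(phi)); d/dphi = P_i*(1 + (k-1)*f_i')
    du1 <- P1 * (1 + (k - 1) * s1)
    du2 <- P2 * (1 + (k - 1) * s2)
    dtr1 <- P1 * (s1 - 1)
    dtr2 <- P2 * (s2 - 1)
    matrix(c(du1, -dtr2,
             dtr1, -du2), nrow = 2, byrow = TRUE)
  }

  sols <- list()
  degen_hits <- 0L
  for (r in seq_len(min(nrow(cells), 4L * grid_n))) {
    i <- cells$i[r]; j <- cells$j[r]
    x <- c(mean(phi[c(i, i + 1L)]), mean(phi[c(j, j + 1L)]))
    res <- newton_in_box(g_fun, jac_fun,
                         x, lo = c(phi[i], phi[j]),
                         hi = c(phi[i + 1L], phi[j + 1L]), tol = tol)
    if (is.null(res)) next
    if (res$rcond < 1e-8) { degen_hits <- degen_hits + 1L; next }
    sols[[length(sols) + 1L]] <- res$x
  }
  list(solutions = sols, degenerate = degenerate || degen_hits > 0L)
}

# Cells of the grid where both separable residuals change sign among the
# four corners. Returns a data.frame of lower-left corner indices.
candidate_cells <- function(a1, b1, a2, b2) {
  n <- length(a1)
  ii <- seq_len(n - 1L)
  # G(i,j) = a[i] - b[j]; over cell (i..i+1, j..j+1) the min/max corners are
  # min(a_i, a_{i+1}) - max(b_j, b_{j+1}) and max(a) - min(b).
  a1lo <- pmin(a1[ii], a1[ii + 1L]); a1hi <- pmax(a1[ii], a1[ii + 1L])
  b1lo <- pmin(b1[ii], b1[ii + 1L]); b1hi <- pmax(b1[ii], b1[ii + 1L])
  a2lo <- pmin(a2[ii], a2[ii + 1L]); a2hi <- pmax(a2[ii], a2[ii + 1L])
  b2lo <- pmin(b2[ii], b2[ii + 1L]); b2hi <- pmax(b2[ii], b2[ii + 1L])
  # cell straddles G1 = 0  <=>  a1lo[i] <= b1hi[j] && a1hi[i] >= b1lo[j]
  m1 <- outer(a1lo, b1hi, `<=`) & outer(a1hi, b1lo, `>=`)
  m2 <- outer(a2lo, b2hi, `<=`) & outer(a2hi, b2lo, `>=`)
  hit <- which(m1 & m2, arr.ind = TRUE)
  data.frame(i = hit[, 1L], j = hit[, 2L])
}

# Damped Newton within (an inflation of) a grid cell. Returns NULL when it
# fails to converge, otherwise list(x, rcond).
newton_in_box <- function(g_fun, jac_fun, x, lo, hi, tol,
                          max_iter = 80L, inflate = 3) {
  span <- hi - lo
  blo <- pmax(lo - inflate * span, 1e-9)
  bhi <- pmin(hi + inflate * span, 1 - 1e-9)
  g <- g_fun(x)
  rc <- NA_real_
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol) {
      J <- jac_fun(x)
      rc <- rcond_2x2(J)
      return(list(x = x, rcond = rc))
    }
    J <- jac_fun(x)
    rc <- rcond_2x2(J)
    if (!is.finite(rc) || rc < 1e-14) return(NULL)
    step <- solve_2x2(J, g)
    lambda <- 1
    repeat {
      xn <- pmin(pmax(x - lambda * step, blo), bhi)
      gn <- g_fun(xn)
      if (sum(gn^2) < sum(g^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) == 0 && max(abs(gn)) >= tol) return(NULL)
    x <- xn; g <- gn
  }
  if (max(abs(g)) < tol) list(x = x, rcond = rc) else NULL
}

solve_2x2 <- function(J, g) {
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  c(J[2, 2] * g[1] - J[1, 2] * g[2],
    -J[2, 1] * g[1] + J[1, 1] * g[2]) / det
}

rcond_2x2 <- function(J) {
  s <- svd(J, nu = 0, nv = 0)$d
  if (s[1] == 0) 0 else s[2] / s[1]
}

#' Find all 1:1 phase-locked modes of a two-neuron circuit
#'
#' Scans the two periodicity residuals over a phase grid for each feedback
#' index `k = 1..k_max`, refines every sign-change cell to a root, and
#' annotates each locking with its intervals, time lags, network period,
#' stability verdict (see [assess_stability()]) and mode class. Time lags
#' follow `tl_1 = (ts_1 - delay_21) mod P_N` (interval from a neuron-1 spike
#' to the next neuron-2 spike) and `tl_2 = P_N - tl_1`.
#'
#' @inheritParams interval_curves
#' @param k_max largest feedback index searched.
#' @param grid_n scan resolution per axis.
#' @param class_tol mode classification tolerance as a fraction of the
#'   network period: synchrony if `min(tl)/P_N < class_tol`, antiphase if
#'   `|tl_1 - tl_2|/P_N < class_tol`.
#' @param junction_tol synchronous lockings within this distance of phase 0
#'   or 1 trigger the endpoint-discontinuity rule for inhibitory PRCs.
#' @return tibble with one row per mode: `k`, `phi1`, `phi2`, `ts1`, `tr1`,
#'   `ts2`, `tr2`, `tl1`, `tl2`, `period`, `stable`, `mode_class`, `flags`;
#'   attribute `degenerate` is TRUE when a residual vanished along a
#'   continuum (uncoupled limit) rather than transversally.
#' @export
#' @examples
#' circ <- make_circuit(make_template("exc_I", noise = FALSE), period_a = 1)
#' find_lockings(circ, delay = 0.40)
find_lockings <- function(spec, delay = NULL, k_max = 3L, grid_n = 800L,
                          class_tol = 0.02, junction_tol = 0.02) {
  stopifnot(inherits(spec, "circuit_spec"), k_max >= 1L)
  spec <- override_delay(spec, delay)
  p_slow <- max(spec$P1, spec$P2)

  all_sols <- list()
  degenerate <- FALSE
  for (k in seq_len(k_max)) {
    sk <- solve_k(spec, k, grid_n = grid_n)
    degenerate <- degenerate || sk$degenerate
    for (x in sk$solutions) {
      all_sols[[length(all_sols) + 1L]] <- c(k = k, phi1 = x[1], phi2 = x[2])
    }
  }
  rows <- dedup_modes(all_sols)
  out <- mode_table(spec, rows, class_tol = class_tol,
                    junction_tol = junction_tol)
  attr(out, "degenerate") <- degenerate
  attr(out, "p_slow") <- p_slow
  out
}

# Deduplicate (phi1, phi2) pairs across k by proximity.
dedup_modes <- function(sols, tol = 1e-6) {
  if (length(sols) == 0L) return(NULL)
  m <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    if (i < nrow(m)) {
      later <- seq(i + 1L, nrow(m))
      dup <- abs(m[later, "phi1"] - m[i, "phi1"]) < tol &
        abs(m[later, "phi2"] - m[i, "phi2"]) < tol
      keep[later][dup] <- FALSE
    }
  }
  m[keep, , drop = FALSE]
}

mode_table <- function(spec, rows, class_tol, junction_tol) {
  cols <- c("k", "phi1", "phi2", "ts1", "tr1", "ts2", "tr2",
            "tl1", "tl2", "period")
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), ncol = length(cols))), cols))
    out$stable <- logical(0)
    out$mode_class <- character(0)
    out$flags <- character(0)
    return(out)
  }
  n <- nrow(rows)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    k <- unname(rows[i, "k"])
    phi1 <- unname(rows[i, "phi1"])
    phi2 <- unname(rows[i, "phi2"])
    ts1 <- ts_fun(spec$P1, phi1); tr1 <- tr_fun(spec$P1, spec$prc1, phi1)
    ts2 <- ts_fun(spec$P2, phi2); tr2 <- tr_fun(spec$P2, spec$prc2, phi2)
    pn <- ts1 + tr1
    tl1 <- (ts1 - spec$delay_21) %% pn
    tl2 <- pn - tl1
    cls <- classify_mode(spec, tl1, tl2, pn, class_tol)
    st <- stability_verdict(spec, k, phi1, phi2, cls, junction_tol)
    res[[i]] <- tibble::tibble(
      k = as.integer(k), phi1 = phi1, phi2 = phi2,
      ts1 = ts1, tr1 = tr1, ts2 = ts2, tr2 = tr2,
      tl1 = tl1, tl2 = tl2, period = pn,
      stable = st$stable, mode_class = cls, flags = st$flags
    )
  }
  do.call(rbind, res)
}

classify_mode <- function(spec, tl1, tl2, pn, class_tol) {
  if (min(tl1, tl2) / pn < class_tol) return("synchrony")
  if (abs(tl1 - tl2) / pn < class_tol) return("antiphase")
  dbar <- (spec$delay_12 + spec$delay_21) / 2
  if (abs(min(tl1, tl2) - dbar) / pn < 2 * class_tol) return("leader_follower")
  "other"
}

#' Stability of a 1:1 locked mode
#'
#' Applies the graphical slope-comparison rule: the locking is stable when
#' the emitting neuron's interval curve is steeper than the partner's at the
#' intersection, which in terms of the PRC slopes `s_i = f_i'(phi_i)` reads
#' `|(1 - s1)(1 - s2)| < |(1 + (k-1) s1)(1 + (k-1) s2)|`. Synchronous modes
#' must additionally satisfy `|1 - (s1 + s2)| < 1` (perturbations from
#' synchrony engage both inputs in the same cycle). Two overrides:
#' a synchronous locking with both points on the causal-limit branch is
#' neutrally stable in theory and is reported stable with flag
#' `neutral_at_limit`; an inhibitory PRC with an endpoint discontinuity
#' `f(1-) > f(0+)` destabilizes synchrony when the locking phase sits within
#' `junction_tol` of 0 or 1 (flag `discontinuity`), because the neuron that
#' fires late receives the strongly delaying late-phase input - a short
#' conduction delay moves the locking point off the discontinuity and
#' restores slope-based stability.
#'
#' @param mode one-row tibble (or list) with at least `k`, `phi1`, `phi2`,
#'   `tl1`, `tl2`, `period` as produced by [find_lockings()].
#' @param spec the [make_circuit()] specification the mode belongs to.
#' @param class_tol,junction_tol as in [find_lockings()].
#' @return logical; attribute `"flags"` carries the override annotations.
#' @export
assess_stability <- function(mode, spec, class_tol = 0.02,
                             junction_tol = 0.02) {
  stopifnot(inherits(spec, "circuit_spec"))
  cls <- classify_mode(spec, mode$tl1, mode$tl2, mode$period, class_tol)
  st <- stability_verdict(spec, mode$k, mode$phi1, mode$phi2, cls,
                          junction_tol)
  structure(st$stable, flags = st$flags)
}

stability_verdict <- function(spec, k, phi1, phi2, mode_class, junction_tol) {
  s1 <- prc_slope(spec$prc1, phi1)
  s2 <- prc_slope(spec$prc2, phi2)
  flags <- character(0)

  stable <- abs((1 - s1) * (1 - s2)) <
    abs((1 + (k - 1) * s1) * (1 + (k - 1) * s2))

  if (mode_class == "synchrony") {
    clamped1 <- prc_clamped(spec$prc1, phi1)
    clamped2 <- prc_clamped(spec$prc2, phi2)
    if (clamped1 && clamped2) {
      # exactly on the causal limit synchrony is neutrally stable in theory;
      # physically some latency always remains, so report stable + flag
      stable <- TRUE
      flags <- c(flags, "neutral_at_limit")
    } else {
      stable <- stable && abs(1 - (s1 + s2)) < 1
    }
    near_junction <- function(phi) min(phi, 1 - phi) < junction_tol
    gap1 <- prc_endpoint_gap(spec$prc1)
    gap2 <- prc_endpoint_gap(spec$prc2)
    if (spec$coupling_sign == "inhibitory" &&
        ((gap1 > 1e-6 && near_junction(phi1)) ||
         (gap2 > 1e-6 && near_junction(phi2)))) {
      stable <- FALSE
      flags <- c(flags, "discontinuity")
    }
  }
  list(stable = stable,
       flags = if (length(flags)) paste(flags, collapse = ";") else "")
}

#' Sweep the conduction delay and collect locked modes
#'
#' Applies [find_lockings()] at each normalized delay of a grid (delays are
#' normalized by the slower neuron's intrinsic period). Output lags and
#' periods are normalized the same way; `tl1_signed`/`tl2_signed` carry the
#' signed-lag representation (lag 1 positive, lag 2 negative) used for
#' bifurcation-style diagrams.
#'
#' @inheritParams find_lockings
#' @param delays_norm numeric grid of normalized delays, within `[0, 1.2]`.
#' @param stable_only drop unstable modes from the result.
#' @return tibble with `delay_norm` plus the [find_lockings()] columns and
#'   `tl1_norm`, `tl2_norm`, `period_norm`, `tl1_signed`, `tl2_signed`.
#' @export
delay_sweep <- function(spec, delays_norm = seq(0, 1, by = 0.02),
                        k_max = 3L, grid_n = 800L, class_tol = 0.02,
                        junction_tol = 0.02, stable_only = FALSE) {
  stopifnot(all(delays_norm >= 0), all(delays_norm <= 1.2))
  p_slow <- max(spec$P1, spec$P2)
  out <- lapply(delays_norm, function(dn) {
    modes <- find_lockings(spec, delay = dn * p_slow, k_max = k_max,
                           grid_n = grid_n, class_tol = class_tol,
                           junction_tol = junction_tol)
    if (nrow(modes) == 0L) return(NULL)
    modes$delay_norm <- dn
    modes
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(tibble::tibble(delay_norm = numeric(0)))
  }
  if (stable_only) out <- out[out$stable, , drop = FALSE]
  out$tl1_norm <- out$tl1 / p_slow
  out$tl2_norm <- out$tl2 / p_slow
  out$period_norm <- out$period / p_slow
  out$tl1_signed <- out$tl1_norm
  out$tl2_signed <- -out$tl2_norm
  out[, c("delay_norm", setdiff(names(out), "delay_norm"))]
}

#' Near-synchronous time lag under small heterogeneity
#'
#' For two neurons with (nearly) identical PRCs, a small intrinsic-period
#' difference `dP = P1 - P2` and/or a small delay difference
#' `ddelta = delay_12 - delay_21` perturb exact synchrony into a locking
#' with a small time lag. Linearizing both PRCs about the homogeneous
#' locking point `phi* = mean delay / mean period` gives
#'
#'   eps = ddelta/2 - dP * (1 + f(phi*) - phi* f'(phi*)) / (2 f'(phi*))
#'
#' where `eps > 0` means neuron 2 fires after neuron 1. For identical
#' neurons the fraction's numerator vanishes, allowing exact synchrony when
#' the delays are equal; on the causal-limit branch (`f = phi - 1`,
#' `f' = 1`) the numerator vanishes identically whatever the periods, and
#' the lag reduces to `ddelta/2` exactly.
#'
#' @param spec a [make_circuit()] specification with small period and delay
#'   differences.
#' @return time lag `eps` in ms.
#' @export
heterogeneity_lag <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  pbar <- (spec$P1 + spec$P2) / 2
  dbar <- (spec$delay_12 + spec$delay_21) / 2
  ddelta <- spec$delay_12 - spec$delay_21
  dP <- spec$P1 - spec$P2
  phi_star <- dbar / pbar
  if (phi_star >= 1) {
    stop("mean delay exceeds the mean period: no first-cycle synchronous ",
         "locking point", call. = FALSE)
  }
  clamped <- prc_clamped(spec$prc1, phi_star) &&
    prc_clamped(spec$prc2, phi_star)
  s <- mean(c(prc_slope(spec$prc1, phi_star), prc_slope(spec$prc2, phi_star)))
  f <- mean(c(evaluate_prc(spec$prc1, phi_star),
              evaluate_prc(spec$prc2, phi_star)))
  if (!clamped && !(abs(1 - 2 * s) < 1)) {
    stop("synchronous locking at phi* = ", signif(phi_star, 4),
         " is not stable; the linearized lag is undefined", call. = FALSE)
  }
  if (clamped) {
    # on the causal limit 1 + f - phi*·f' = 1 + (phi*-1) - phi* is exactly 0
    return(ddelta / 2)
  }
  if (s == 0) {
    stop("zero PRC slope at the locking point: no restoring force, ",
         "heterogeneity lag undefined", call. = FALSE)
  }
  ddelta / 2 - dP * (1 + f - phi_star * s) / (2 * s)
}
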