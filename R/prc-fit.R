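# Fitting PRC models from noisy (phase, resetting) measurements.

#' Construct a PRC measurement set
#'
#' Raw (stimulus phase, normalized resetting) pairs as produced by the
#' dynamic-clamp stimulation protocol (or its synthetic emulation in
#' [generate_measurements()]).
#'
#' @param phase numeric vector of stimulus phases in `[0, 1)`.
#' @param resetting numeric vector of normalized period changes
#'   `(P_j - P_i)/P_i`; each value must satisfy causality
#'   `resetting >= phase - 1`.
#' @param coupling_sign `"excitatory"` or `"inhibitory"`.
#' @param intrinsic_period free-running period of the measured cell, ms.
#' @return object of class `prc_measurements` with a `records` tibble.
#' @export
prc_measurements <- function(phase, resetting,
                             coupling_sign = c("excitatory", "inhibitory"),
                             intrinsic_period = 100) {
  coupling_sign <- match.arg(coupling_sign)
  check_phase(phase)
  stopifnot(length(phase) == length(resetting),
            is.numeric(resetting), all(is.finite(resetting)),
            intrinsic_period > 0)
  if (any(resetting < phase - 1 - 1e-12)) {
    stop("causality violated: resetting < phase - 1 for some records",
         call. = FALSE)
  }
  structure(
    list(
      records = tibble::tibble(phase = as.numeric(phase),
                               resetting = as.numeric(resetting)),
      coupling_sign = coupling_sign,
      intrinsic_period = intrinsic_period
    ),
    class = "prc_measurements"
  )
}

#' @export
print.prc_measurements <- function(x, ...) {
  cat(sprintf("<prc_measurements> %d records, %s, P = %g ms\n",
              nrow(x$records), x$coupling_sign, x$intrinsic_period))
  invisible(x)
}

#' Bin phase resetting measurements
#'
#' Measurements are divided evenly into `n_bins` phase bins. Any bin holding
#' fewer than `min_per_bin` values is expanded symmetrically to include its
#' immediate neighbors on both sides (then wider windows if still deficient)
#' and the pooled values are averaged instead; the pooled bin is centered at
#' the value-weighted mean phase. Fails only if the whole set cannot fill a
#' window.
#'
#' @param phase,resetting numeric vectors.
#' @param n_bins number of equal-width bins on `[0, 1)`.
#' @param min_per_bin minimum number of values per bin.
#' @return tibble with columns `phase` (bin center), `mean`, `sd`, `n`,
#'   `merged` (logical), one row per non-empty nominal bin.
#' @export
bin_resetting <- function(phase, resetting, n_bins = 100L, min_per_bin = 3L) {
  stopifnot(length(phase) == length(resetting), n_bins >= 2L)
  idx <- pmin(pmax(floor(phase * n_bins) + 1L, 1L), n_bins)
  counts <- tabulate(idx, n_bins)
  rows <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    if (counts[b] == 0L) next  # nothing measured here, nothing to pool around
    width <- 0L
    repeat {
      lo <- max(1L, b - width)
      hi <- min(n_bins, b + width)
      sel <- idx >= lo & idx <= hi
      if (sum(sel) >= min_per_bin) break
      if (lo == 1L && hi == n_bins) {
        stop("bin ", b, " cannot reach ", min_per_bin,
             " values even after merging all neighbors", call. = FALSE)
      }
      width <- width + 1L
    }
    v <- resetting[sel]
    rows[[b]] <- c(
      phase = if (width > 0L) mean(phase[sel]) else (b - 0.5) / n_bins,
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0,
      n = length(v),
      merged = width > 0L
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  tibble::tibble(phase = out[, "phase"], mean = out[, "mean"],
                 sd = out[, "sd"], n = as.integer(out[, "n"]),
                 merged = out[, "merged"] > 0)
}

# Least-squares polynomial fit of given degree to (x, y); ascending coeffs.
fit_poly_ls <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  unname(fit$coefficients)
}

#' Fit a PRC model to a measurement set
#'
#' Measurements are binned with [bin_resetting()]; polynomials of degree 2,
#' 3 and 4 (up to `max_degree`) are fit to the binned means by least squares
#' and the degree is selected by AIC (ties favor the lower degree). Noise
#' envelopes are polynomials of the selected degree fit to the binned
#' mean +/- sd. For excitatory sets, isolated positive (delay) values at very
#' late phases are excluded before fitting: late advances larger than the
#' time remaining to the next spike cannot be observed, which biases late
#' measurements toward spurious small delays.
#'
#' @param samples a [prc_measurements()] set with at least `min_samples`
#'   records.
#' @param max_degree highest polynomial degree tried (2-4).
#' @param n_bins,min_per_bin binning parameters, see [bin_resetting()].
#' @param spurious_late_phase excitatory-only filter threshold: records with
#'   `phase > spurious_late_phase` and `resetting > 0` are dropped.
#' @param min_samples minimum number of records required.
#' @return a [prc_model()] with attributes `fit_degree`, `fit_aic` (named
#'   vector over candidate degrees), `n_dropped_spurious`, `n_bins_merged`
#'   and `envelope_ok` (FALSE flags a fitted upper envelope dipping below the
#'   mean or mean below lower anywhere on the grid).
#' @export
fit_prc <- function(samples, max_degree = 4L, n_bins = 100L,
                    min_per_bin = 3L, spurious_late_phase = 0.9,
                    min_samples = 300L) {
  stopifnot(inherits(samples, "prc_measurements"))
  rec <- samples$records
  if (nrow(rec) < min_samples) {
    stop("need at least ", min_samples, " samples to fit a PRC, got ",
         nrow(rec), call. = FALSE)
  }
  if (max_degree < 2L || max_degree > 4L) {
    stop("`max_degree` must be 2, 3 or 4", call. = FALSE)
  }
  n_spur <- 0L
  if (samples$coupling_sign == "excitatory") {
    spur <- rec$phase > spurious_late_phase & rec$resetting > 0
    n_spur <- sum(spur)
    rec <- rec[!spur, , drop = FALSE]
  }
  bins <- bin_resetting(rec$phase, rec$resetting, n_bins, min_per_bin)

  degrees <- 2:max_degree
  aic <- vapply(degrees, function(d) {
    res <- bins$mean - poly_eval(fit_poly_ls(bins$phase, bins$mean, d),
                                 bins$phase)
    n <- length(res)
    # Gaussian AIC: d+1 coefficients plus the residual variance
    n * log(sum(res^2) / n) + 2 * (d + 2)
  }, numeric(1))
  names(aic) <- degrees
  degree <- degrees[which.min(aic)]  # which.min takes the first (lowest) tie

  mean_c <- fit_poly_ls(bins$phase, bins$mean, degree)
  up_c <- fit_poly_ls(bins$phase, bins$mean + bins$sd, degree)
  lo_c <- fit_poly_ls(bins$phase, bins$mean - bins$sd, degree)

  model <- prc_model(mean_c, up_c, lo_c, coupling_sign = samples$coupling_sign)

  grid <- seq(0, 0.999, length.out = 500)
  env_ok <- all(poly_eval(up_c, grid) >= poly_eval(mean_c, grid) - 1e-9) &&
    all(poly_eval(mean_c, grid) >= poly_eval(lo_c, grid) - 1e-9)

  attr(model, "fit_degree") <- degree
  attr(model, "fit_aic") <- aic
  attr(model, "n_dropped_spurious") <- n_spur
  attr(model, "n_bins_merged") <- sum(bins$merged)
  attr(model, "envelope_ok") <- env_ok
  model
}
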