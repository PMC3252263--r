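# Circular statistics of per-cycle time lags.

#' Circular summary of a lag series
#'
#' Each cycle's time lag is mapped to an angle on the network-period circle,
#' `theta_k = 2*pi*tlag_k / P_network`, pooling the two lag directions
#' (`tl1/P_N` and `1 - tl2/P_N` land on the same circle point in a perfect
#' locking). With `X = mean(cos theta)` and `Y = mean(sin theta)`, the mean
#' network phase is `atan2(Y, X)/(2*pi) mod 1` and the locking strength is
#' `R^2 = X^2 + Y^2`: 1 for a delta-like lag distribution, 0 for lags spread
#' uniformly over the cycle.
#'
#' @param series a [lag_series()] with at least 2 cycles (or a numeric vector
#'   of lags, in which case `p_network` must be given).
#' @param p_network network period used to normalize raw lag vectors; taken
#'   from the series when a `lag_series` is supplied.
#' @param pool `"both"` (default) uses both lag directions; `"tl1"`/`"tl2"`
#'   restrict to one.
#' @return object of class `circular_summary`: list with `mean_phase` (in
#'   `[0, 1)`, `NA` when the resultant has zero length), `R2`, `N`.
#' @export
#' @examples
#' circ <- make_circuit(make_template("exc_II"), period_a = 1)
#' run <- run_map(circ, n_cycles = 500, delay = 0.9, seed = 1)
#' circular_summary(run$lags)
circular_summary <- function(series, p_network = NULL,
                             pool = c("both", "tl1", "tl2")) {
  pool <- match.arg(pool)
  if (inherits(series, "lag_series")) {
    pn <- series$p_network
    lags <- switch(pool,
                   both = c(series$lags$tl1, -series$lags$tl2),
                   tl1 = series$lags$tl1,
                   tl2 = -series$lags$tl2)
    n_cycles <- nrow(series$lags)
  } else {
    stopifnot(is.numeric(series), !is.null(p_network))
    pn <- p_network
    lags <- series
    n_cycles <- length(series)
  }
  if (n_cycles < 2L) stop("need at least 2 cycles", call. = FALSE)
  theta <- 2 * pi * lags / pn
  X <- mean(cos(theta))
  Y <- mean(sin(theta))
  R2 <- X^2 + Y^2
  mean_phase <- if (R2 < 1e-24) NA_real_ else (atan2(Y, X) / (2 * pi)) %% 1
  structure(
    list(mean_phase = mean_phase, R2 = R2, N = n_cycles),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary> mean phase %.4g, R^2 = %.4g (N = %d)\n",
              x$mean_phase, x$R2, x$N))
  invisible(x)
}

#' Wrap a network phase to the branch centered on (-0.25, 0.75]
#'
#' Convenience for reporting: near-synchronous phases come out as small
#' signed values around 0 instead of flipping between 0+ and 1-, while
#' antiphase remains 0.5.
#'
#' @param phase numeric vector of phases.
#' @return numeric vector in `(-0.25, 0.75]`.
#' @export
wrap_phase <- function(phase) {
  ((phase + 0.25) %% 1) - 0.25
}
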