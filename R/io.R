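# Plain-text interchange formats: PRC sample CSV, PRC model JSON, circuit
# JSON, sweep/lag/histogram CSV.

#' Read a PRC sample CSV
#'
#' Expects a header row with columns `phase,resetting`.
#'
#' @param path file path.
#' @param coupling_sign,intrinsic_period metadata not carried by the CSV.
#' @return a [prc_measurements()] set.
#' @export
read_prc_samples <- function(path,
                             coupling_sign = c("excitatory", "inhibitory"),
                             intrinsic_period = 100) {
  df <- utils::read.csv(path)
  if (!all(c("phase", "resetting") %in% names(df))) {
    stop("'", path, "' must have columns phase,resetting", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("'", path, "' has no records", call. = FALSE)
  prc_measurements(df$phase, df$resetting,
                   coupling_sign = match.arg(coupling_sign),
                   intrinsic_period = intrinsic_period)
}

#' Write a PRC sample CSV
#' @param samples a [prc_measurements()] set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prc_samples <- function(samples, path) {
  stopifnot(inherits(samples, "prc_measurements"))
  utils::write.csv(samples$records, path, row.names = FALSE)
  invisible(path)
}

model_to_list <- function(model) {
  list(
    coupling_sign = model$coupling_sign,
    prc_type = model$prc_type,
    mean_coeffs = model$mean_coeffs,
    sigma_upper_coeffs = model$sigma_upper_coeffs,
    sigma_lower_coeffs = model$sigma_lower_coeffs,
    endpoint_values = as.list(model$endpoint_values)
  )
}

model_from_list <- function(x) {
  prc_model(
    mean_coeffs = as.numeric(x$mean_coeffs),
    sigma_upper_coeffs = as.numeric(x$sigma_upper_coeffs),
    sigma_lower_coeffs = as.numeric(x$sigma_lower_coeffs),
    coupling_sign = x$coupling_sign,
    prc_type = x$prc_type
  )
}

#' Write a PRC model to JSON
#' @param model a [prc_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prc_model <- function(model, path) {
  stopifnot(inherits(model, "prc_model"))
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a PRC model from JSON
#' @param path file written by [write_prc_model()].
#' @return a [prc_model()].
#' @export
read_prc_model <- function(path) {
  model_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a circuit specification to JSON
#' @param spec a [make_circuit()] specification.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(spec, path) {
  stopifnot(inherits(spec, "circuit_spec"))
  jsonlite::write_json(
    list(
      period_a_ms = spec$P1,
      period_b_ms = spec$P2,
      delay_ab_ms = spec$delay_12,
      delay_ba_ms = spec$delay_21,
      coupling_sign = spec$coupling_sign,
      prc_a = model_to_list(spec$prc1),
      prc_b = model_to_list(spec$prc2)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a circuit specification from JSON
#' @param path file written by [write_circuit()].
#' @return a `circuit_spec`.
#' @export
read_circuit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- make_circuit(
    prc_a = model_from_list(x$prc_a),
    prc_b = model_from_list(x$prc_b),
    period_a = x$period_a_ms,
    delay = (x$delay_ab_ms + x$delay_ba_ms) / 2,
    delta_delay = x$delay_ab_ms - x$delay_ba_ms
  )
  spec$P2 <- x$period_b_ms
  spec
}
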