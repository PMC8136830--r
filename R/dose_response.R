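#' Dose-response curves
#'
#' A dose-response curve pairs a strictly increasing input grid with the
#' circuit output at each input. `dose_response()` builds one from raw
#' vectors; [simulate_dose_response()] builds one from a circuit model.
#'
#' @param input Strictly increasing input values. Metrics that work on the
#'   logarithmic axis ([sensitivity_curve()], [compute_mdl()],
#'   [compute_threshold()]) additionally require them to be positive.
#' @param output Output values, same length as `input`, >= 0.
#' @param input_name,output_name Axis labels carried along for plotting and
#'   serialization.
#'
#' @return A tibble of class `dose_response` with columns `input` and
#'   `output`.
#' @examples
#' dr <- dose_response(c(0.1, 1, 10), c(1, 5.5, 9.9))
#' compute_fca(dr)
#' @export
dose_response <- function(input, output,
                          input_name = "input", output_name = "output") {
  if (length(input) == 0L) abort("`input` grid must be non-empty.")
  if (length(input) != length(output)) {
    abort("`input` and `output` must have the same length.")
  }
  if (anyNA(input) || anyNA(output)) abort("missing values are not allowed.")
  if (length(input) > 1L && any(diff(input) <= 0)) {
    abort("`input` must be strictly increasing.")
  }
  if (any(output < 0)) abort("`output` values must be >= 0.")
  out <- tibble(input = as.numeric(input), output = as.numeric(output))
  attr(out, "input_name") <- input_name
  attr(out, "output_name") <- output_name
  class(out) <- c("dose_response", class(out))
  out
}

as_dose_response <- function(x) {
  if (inherits(x, "dose_response")) return(x)
  if (!is.data.frame(x) || !all(c("input", "output") %in% names(x))) {
    abort("expected a data frame with `input` and `output` columns.")
  }
  dose_response(x$input, x$output)
}

#' Simulate a dose-response curve from a circuit model
#'
#' Vectorizes a circuit's steady state over an input grid, producing the
#' curve objects consumed by the metrics and fitting functions.
#'
#' @param model A circuit model: [hill_put()], [linear_circuit()],
#'   [molecular_circuit()] or [genetic_circuit()].
#' @param inputs Strictly increasing, non-negative input grid.
#' @param ... Passed to the steady-state solver (e.g. `tol`).
#' @return A [dose_response()] tibble.
#' @examples
#' mc <- molecular_circuit("ICF", molecular_params(fs = 0))
#' simulate_dose_response(mc, c(1e-3, 1, 1e3))
#' @export
simulate_dose_response <- function(model, inputs, ...) {
  UseMethod("simulate_dose_response")
}

check_input_grid <- function(inputs) {
  if (length(inputs) == 0L) abort("`inputs` grid must be non-empty.")
  if (anyNA(inputs) || any(inputs < 0)) {
    abort("`inputs` must be non-negative and non-missing.")
  }
  if (length(inputs) > 1L && any(diff(inputs) <= 0)) {
    abort("`inputs` must be strictly increasing.")
  }
  as.numeric(inputs)
}

#' @export
simulate_dose_response.hill_put <- function(model, inputs, ...) {
  inputs <- check_input_grid(inputs)
  dose_response(inputs, put_transfer(inputs, model))
}

#' Logarithmically spaced input grid
#'
#' @param from,to Positive grid end points.
#' @param n Number of points.
#' @return Numeric vector of length `n`, log-spaced, strictly increasing.
#' @export
log_grid <- function(from = 1e-3, to = 1e3, n = 200) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}
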