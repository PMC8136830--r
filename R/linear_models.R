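#' Linear block models of OL, ICF and DNF circuits
#'
#' In the linear block models every operation around the promoter under test
#' is linear (subtraction, gain, inversion), and only the PUT itself is a
#' monotone nonlinear transfer with basal level `beta` and maximum 1. The
#' three wirings of the subtraction branch are:
#'
#' * **OL** (open loop): a constant subtraction,
#'   \eqn{out = p - F_s};
#' * **ICF** (indirect coherent feedforward, coherent feedforward type 4):
#'   the subtracted branch is itself driven by the inverted PUT output,
#'   \eqn{out = p - F_s (1 - p) = p(1 + F_s) - F_s};
#' * **DNF** (mutual inhibition through double negative feedback): the output
#'   feeds back through an inverter, the fixed point of
#'   \eqn{out = p - F_s (1 - out)}, i.e. \eqn{out = (p - F_s)/(1 - F_s)}
#'   (requires \eqn{F_s < 1}).
#'
#' Because physical signals cannot fall below zero and a real readout has a
#' measurement noise floor, outputs are clipped from below at `floor`
#' (epsilon). The floor is what makes fold-change activation finite once the
#' basal output is driven to zero, and produces the FCA plateau as `fs`
#' grows past its optimum.
#'
#' @param topology One of `"OL"`, `"ICF"`, `"DNF"`.
#' @param fs Loop/subtraction strength, >= 0. For DNF, `fs < 1` (a feedback
#'   gain of one or more diverges).
#' @param put A [hill_put()] describing the promoter under test.
#' @param floor Output floor epsilon, >= 0 (default `1e-3`).
#'
#' @return An object of class `linear_circuit`.
#' @examples
#' lc <- linear_circuit("ICF", fs = 1 / 9, put = hill_put(0.1, 1.5))
#' simulate_dose_response(lc, log_grid(1e-3, 1e3, 7))
#' @export
linear_circuit <- function(topology = c("OL", "ICF", "DNF"), fs = 0,
                           put = hill_put(), floor = 1e-3) {
  topology <- match.arg(topology)
  if (!is.numeric(fs) || length(fs) != 1L || fs < 0) {
    abort("`fs` must be a single non-negative number.")
  }
  if (topology == "DNF" && fs >= 1) {
    abort("DNF requires `fs` < 1: a feedback gain at or above unity diverges.")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0) {
    abort("`floor` must be a single non-negative number.")
  }
  stopifnot(inherits(put, "hill_put"))
  structure(list(topology = topology, fs = fs, put = put, floor = floor),
            class = "linear_circuit")
}

#' @export
print.linear_circuit <- function(x, ...) {
  cat(sprintf("<linear_circuit> %s, fs = %g, beta = %g, n = %g, floor = %g\n",
              x$topology, x$fs, x$put$beta, x$put$n, x$floor))
  invisible(x)
}

#' Linear circuit output for a given PUT activity
#'
#' Maps the PUT activity `p` (in \[beta, 1\]) through the linear wiring of a
#' circuit. Both ICF and DNF preserve the maximum: at `p = 1` the output is
#' exactly 1 for every valid `fs`.
#'
#' @param p PUT activity value(s) in \[0, 1\].
#' @param circuit A [linear_circuit()].
#' @return Numeric output value(s), floored at `circuit$floor`.
#' @examples
#' linear_response(0.5, linear_circuit("OL", fs = 0.2, floor = 0)) # 0.3
#' @export
linear_response <- function(p, circuit) {
  stopifnot(inherits(circuit, "linear_circuit"))
  if (!is.numeric(p) || any(p < 0) || any(p > 1) || anyNA(p)) {
    abort("`p` must lie in [0, 1].")
  }
  fs <- circuit$fs
  raw <- switch(circuit$topology,
    OL  = p - fs,
    ICF = p * (1 + fs) - fs,
    DNF = (p - fs) / (1 - fs)
  )
  pmax(circuit$floor, raw)
}

#' @export
simulate_dose_response.linear_circuit <- function(model, inputs, ...) {
  inputs <- check_input_grid(inputs)
  p <- put_transfer(inputs, model$put)
  dose_response(inputs, linear_response(p, model))
}

#' Optimal loop strength of the linear circuit models
#'
#' The loop strength that drives the basal output to zero while leaving the
#' maximum untouched, simultaneously maximizing FCA and minimizing MDL:
#' \eqn{F_s^* = \beta / (1 - \beta)} for ICF and \eqn{F_s^* = \beta} for DNF.
#' The OL circuit has no FCA-improving optimum (subtraction lowers ON and OFF
#' alike), so `NA` is returned for it.
#'
#' @param topology One of `"OL"`, `"ICF"`, `"DNF"`.
#' @param beta Basal level of the PUT, in (0, 1).
#' @return The optimal `fs` (a number), or `NA_real_` for `"OL"`.
#' @examples
#' linear_optimal_fs("ICF", 0.1) # 1/9
#' linear_optimal_fs("DNF", 0.1) # 0.1
#' @export
linear_optimal_fs <- function(topology = c("OL", "ICF", "DNF"), beta) {
  topology <- match.arg(topology)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    abort("`beta` must be a single number in (0, 1).")
  }
  switch(topology,
    OL  = NA_real_,
    ICF = beta / (1 - beta),
    DNF = beta
  )
}
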