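#' Parameters of the four-node genetic circuit models
#'
#' The genetic implementations add the concrete regulatory parts to the
#' three-node motif: the promoter under test drives both the reporter and a
#' TetR repressor; TetR represses a PtetO promoter expressing LuxR; LuxR (with
#' AHL, folded into the single knob `fs`) drives a reverse Plux promoter whose
#' transcriptional interference subtracts from the reporter output.
#'
#' Node equations for input `x`:
#' * PUT activity: `p = put_transfer(x, put)`;
#' * TetR: `t = theta * p` (ICF wiring) or `t = max(0, theta * p - w)`
#'   (DNF wiring, where the reverse promoter also interferes with TetR);
#' * effective TetR after aTc sequestration: `t_eff = t / (1 + atc)`;
#' * LuxR: `L = lambda / (1 + t_eff^q)`;
#' * reverse-promoter drive: `w = fs * L`;
#' * output: `z = max(floor, alpha * p - w)` in `"subtractive"` mode
#'   (transcriptional interference as subtraction, the default), or
#'   `z = alpha * p / (1 + w^m)` in `"divisive"` mode (Hill repression,
#'   kept as an option for sensitivity analysis).
#'
#' The default parameter set is the shipped reference configuration: with it,
#' fold-change activation has an interior optimum in `fs` for both the ICF
#' and DNF wirings.
#'
#' @param put A [hill_put()] for the promoter under test.
#' @param alpha Output expression scale, > 0.
#' @param theta TetR expression gain, > 0 (0 allowed to sever the cascade).
#' @param q TetR-PtetO Hill coefficient, > 0.
#' @param lambda LuxR expression scale, > 0.
#' @param atc Dimensionless aTc level, >= 0; reduces active TetR as
#'   `t / (1 + atc)`.
#' @param fs Reverse-promoter strength (proportional to the AHL drive), >= 0.
#' @param mode `"subtractive"` (default) or `"divisive"` interference.
#' @param m Hill coefficient used in divisive mode, > 0.
#' @param floor Output floor epsilon, >= 0.
#'
#' @return An object of class `genetic_params`.
#' @examples
#' genetic_params(fs = 2)
#' @export
genetic_params <- function(put = hill_put(0.1, 1.5), alpha = 10, theta = 5,
                           q = 2, lambda = 1, atc = 0, fs = 0,
                           mode = c("subtractive", "divisive"), m = 2,
                           floor = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(
    inherits(put, "hill_put"),
    is.numeric(alpha), length(alpha) == 1L, alpha > 0,
    is.numeric(theta), length(theta) == 1L, theta >= 0,
    is.numeric(q), length(q) == 1L, q > 0,
    is.numeric(lambda), length(lambda) == 1L, lambda > 0,
    is.numeric(atc), length(atc) == 1L, atc >= 0,
    is.numeric(fs), length(fs) == 1L, fs >= 0,
    is.numeric(m), length(m) == 1L, m > 0,
    is.numeric(floor), length(floor) == 1L, floor >= 0
  )
  structure(list(put = put, alpha = alpha, theta = theta, q = q,
                 lambda = lambda, atc = atc, fs = fs, mode = mode, m = m,
                 floor = floor),
            class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf(
    paste0("<genetic_params> beta = %g, n = %g, alpha = %g, theta = %g, ",
           "q = %g, lambda = %g, atc = %g, fs = %g, mode = %s, floor = %g\n"),
    x$put$beta, x$put$n, x$alpha, x$theta, x$q, x$lambda, x$atc, x$fs,
    x$mode, x$floor))
  invisible(x)
}

genetic_output <- function(p, w, params) {
  if (params$mode == "subtractive") {
    pmax(params$floor, params$alpha * p - w)
  } else {
    params$alpha * p / (1 + w^params$m)
  }
}

genetic_luxr <- function(t, params) {
  t_eff <- t / (1 + params$atc)
  params$lambda / (1 + t_eff^params$q)
}

#' Steady state of the genetic ICF circuit
#'
#' In the ICF wiring TetR is controlled only by the promoter under test, so
#' the whole cascade is feedforward and the steady state is exact.
#'
#' @param x Input value(s), >= 0.
#' @param params A [genetic_params()] object.
#' @return A tibble with columns `x`, `p` (PUT activity), `t` (TetR),
#'   `L` (LuxR), `w` (reverse-promoter drive) and `z` (output).
#' @examples
#' genetic_icf_steady_state(0, genetic_params(fs = 2, floor = 1e-3))
#' @export
genetic_icf_steady_state <- function(x, params = genetic_params()) {
  stopifnot(inherits(params, "genetic_params"))
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    abort("`x` must be non-negative and non-missing.")
  }
  p <- put_transfer(x, params$put)
  t <- params$theta * p
  L <- genetic_luxr(t, params)
  w <- params$fs * L
  tibble(x = as.numeric(x), p = p, t = t, L = L, w = w,
         z = genetic_output(p, w, params),
         converged = TRUE, residual = 0)
}

# scalar DNF fixed point in w on [0, fs * lambda]:
#   w = fs * lambda / (1 + (t(w) / (1 + atc))^q),  t(w) = max(0, theta p - w)
# damped iteration first (damping 0.5), bisection fallback.
genetic_dnf_solve_w <- function(p, params, tol, max_iter) {
  g <- function(w) {
    t <- if (params$mode == "subtractive") {
      max(0, params$theta * p - w)
    } else {
      params$theta * p / (1 + w^params$m)
    }
    params$fs * genetic_luxr(t, params)
  }
  hi <- params$fs * params$lambda
  if (hi == 0) return(list(w = 0, residual = 0, converged = TRUE))
  w <- hi / 2
  for (i in seq_len(max_iter)) {
    w_new <- 0.5 * w + 0.5 * g(w)
    if (abs(w_new - w) < tol && abs(g(w_new) - w_new) < tol) {
      return(list(w = w_new, residual = abs(g(w_new) - w_new),
                  converged = TRUE))
    }
    w <- w_new
  }
  # bisection on h(w) = w - g(w); h(0) <= 0, h(hi) >= 0
  f <- function(w) w - g(w)
  lo <- 0
  flo <- f(lo)
  for (i in seq_len(max_iter)) {
    w <- (lo + hi) / 2
    fw <- f(w)
    if (abs(fw) < tol || (hi - lo) < tol) break
    if (sign(fw) == sign(flo)) { lo <- w; flo <- fw } else hi <- w
  }
  res <- abs(f(w))
  list(w = w, residual = res, converged = res <= max(tol, 1e-10))
}

#' Steady state of the genetic DNF circuit
#'
#' In the DNF wiring the reverse promoter interferes with TetR as well as
#' with the reporter, closing a feedback loop. The steady state is the fixed
#' point of the scalar map in the reverse-promoter drive `w` on
#' `[0, fs * lambda]`, solved by damped iteration (damping 0.5) with a
#' bisection fallback.
#'
#' @inheritParams genetic_icf_steady_state
#' @param tol Fixed-point residual tolerance (default `1e-10`).
#' @param max_iter Iteration budget (default 500).
#' @return As [genetic_icf_steady_state()], plus honest `converged` /
#'   `residual` columns.
#' @export
genetic_dnf_steady_state <- function(x, params = genetic_params(),
                                     tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(params, "genetic_params"), tol > 0)
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    abort("`x` must be non-negative and non-missing.")
  }
  p <- put_transfer(x, params$put)
  sol <- purrr::map(p, genetic_dnf_solve_w, params = params,
                    tol = tol, max_iter = max_iter)
  w <- purrr::map_dbl(sol, "w")
  res <- purrr::map_dbl(sol, "residual")
  conv <- purrr::map_lgl(sol, "converged")
  if (!all(conv)) {
    abort(sprintf(
      "genetic DNF fixed-point solver failed to converge (max residual %.3e).",
      max(res[!conv])))
  }
  t <- if (params$mode == "subtractive") {
    pmax(0, params$theta * p - w)
  } else {
    params$theta * p / (1 + w^params$m)
  }
  tibble(x = as.numeric(x), p = p, t = t, L = genetic_luxr(t, params), w = w,
         z = genetic_output(p, w, params),
         converged = conv, residual = res)
}

#' Genetic circuit model object
#'
#' @param topology `"ICF"` or `"DNF"`.
#' @param params A [genetic_params()] object.
#' @param tol Fixed-point tolerance for the DNF wiring.
#' @return An object of class `genetic_circuit` usable with
#'   [simulate_dose_response()] and [sweep_fs()].
#' @examples
#' gc <- genetic_circuit("ICF", genetic_params(fs = 1))
#' simulate_dose_response(gc, log_grid(1e-3, 1e3, 5))
#' @export
genetic_circuit <- function(topology = c("ICF", "DNF"),
                            params = genetic_params(), tol = 1e-10) {
  topology <- match.arg(topology)
  stopifnot(inherits(params, "genetic_params"))
  structure(list(topology = topology, params = params, tol = tol),
            class = "genetic_circuit")
}

#' @export
print.genetic_circuit <- function(x, ...) {
  cat(sprintf("<genetic_circuit> %s\n", x$topology))
  print(x$params)
  invisible(x)
}

#' @export
simulate_dose_response.genetic_circuit <- function(model, inputs, ...) {
  inputs <- check_input_grid(inputs)
  ss <- switch(model$topology,
    ICF = genetic_icf_steady_state(inputs, model$params),
    DNF = genetic_dnf_steady_state(inputs, model$params, tol = model$tol, ...)
  )
  dose_response(inputs, ss$z)
}
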