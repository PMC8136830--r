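#' Parameters of the three-node molecular circuit models
#'
#' The molecular models replace the linear subtraction by Hill-type
#' repression among three species: the input X, an inhibitor Y and the
#' output Z (all dimensionless, scaled by their dissociation constants).
#' The output is activated by X and repressed by Y,
#' \deqn{z = \alpha \, \frac{x^n + \beta}{1 + x^n} \cdot \frac{1}{1 + y^m},}
#' while the inhibitor is repressed by X (ICF wiring),
#' \deqn{y = \frac{F_s}{1 + x^n},}
#' or, in the DNF wiring, repressed by the output itself,
#' \deqn{y = \frac{F_s}{1 + z^h}.}
#'
#' Defaults are the reference simulation parameter set
#' (beta = 0.1, alpha = 10, n = 1.5, m = 1, h = 1).
#'
#' @param beta Basal level of the activation term, in (0, 1).
#' @param alpha Activation strength of X on Z, > 0.
#' @param n Hill coefficient of activation by X, > 0.
#' @param m Hill coefficient of repression of Z by Y, >= 1.
#' @param h Hill coefficient of repression of Y by Z (DNF only), >= 1.
#' @param fs Loop strength, >= 0.
#'
#' @return An object of class `molecular_params`.
#' @examples
#' molecular_params(fs = 1)
#' @export
molecular_params <- function(beta = 0.1, alpha = 10, n = 1.5,
                             m = 1, h = 1, fs = 0) {
  stopifnot(
    is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0,
    is.numeric(n), length(n) == 1L, n > 0,
    is.numeric(m), length(m) == 1L, m >= 1,
    is.numeric(h), length(h) == 1L, h >= 1,
    is.numeric(fs), length(fs) == 1L, fs >= 0
  )
  structure(list(beta = beta, alpha = alpha, n = n, m = m, h = h, fs = fs),
            class = "molecular_params")
}

#' @export
print.molecular_params <- function(x, ...) {
  cat(sprintf(
    "<molecular_params> beta = %g, alpha = %g, n = %g, m = %g, h = %g, fs = %g\n",
    x$beta, x$alpha, x$n, x$m, x$h, x$fs))
  invisible(x)
}

# activation factor A(x) = alpha * (x^n + beta) / (1 + x^n)
molecular_activation <- function(x, params) {
  xn <- x^params$n
  params$alpha * (xn + params$beta) / (1 + xn)
}

#' Steady state of the molecular ICF circuit
#'
#' The ICF wiring is feedforward, so the steady state is closed-form:
#' `y = fs / (1 + x^n)` and `z = A(x) / (1 + y^m)` with
#' `A(x) = alpha (x^n + beta) / (1 + x^n)`.
#'
#' @param x Dimensionless input value(s), >= 0.
#' @param params A [molecular_params()] object.
#' @return A tibble with columns `x`, `y`, `z`, `converged`, `residual`.
#'   The feedforward solution is exact, so `converged` is always `TRUE` and
#'   `residual` 0.
#' @examples
#' icf_steady_state(0, molecular_params(fs = 1)) # y = 1, z = 0.5
#' @export
icf_steady_state <- function(x, params = molecular_params()) {
  stopifnot(inherits(params, "molecular_params"))
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    abort("`x` must be non-negative and non-missing.")
  }
  y <- params$fs / (1 + x^params$n)
  z <- molecular_activation(x, params) / (1 + y^params$m)
  tibble(x = as.numeric(x), y = y, z = z,
         converged = TRUE, residual = 0)
}

# residual of the DNF fixed point in z, for scalar x
dnf_residual <- function(z, a, params) {
  y <- params$fs / (1 + z^params$h)
  z * (1 + y^params$m) - a
}

# solve one DNF fixed point by bisection on [0, a]; a = A(x) > 0
dnf_solve_one <- function(a, params, tol, max_iter) {
  f <- function(z) dnf_residual(z, a, params)
  multistable <- FALSE
  roots <- NULL
  if (params$m * params$h > 1) {
    # scan for multiple sign changes (DNF motifs can be bistable)
    grid <- c(0, exp(seq(log(max(a * 1e-6, 1e-12)), log(a), length.out = 400)))
    fv <- vapply(grid, f, numeric(1))
    sgn <- sign(fv)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    roots <- vapply(flips, function(i) {
      uniroot(f, c(grid[i], grid[i + 1]), tol = tol / 10)$root
    }, numeric(1))
    if (any(fv == 0)) roots <- sort(unique(c(roots, grid[fv == 0])))
    multistable <- length(roots) > 1L
  }
  if (length(roots) >= 1L) {
    z <- min(roots)
  } else {
    lo <- 0; hi <- a
    flo <- f(lo)
    if (flo > 0) hi <- lo  # a == 0 edge; cannot happen for beta > 0
    for (i in seq_len(max_iter)) {
      z <- (lo + hi) / 2
      fz <- f(z)
      if (abs(fz) < tol || (hi - lo) < tol) break
      if (sign(fz) == sign(flo)) { lo <- z; flo <- fz } else hi <- z
    }
  }
  res <- abs(f(z))
  list(z = z, residual = res, converged = res <= max(tol, 1e-10),
       multistable = multistable)
}

#' Steady state of the molecular DNF circuit
#'
#' The DNF wiring couples the output equation to `y = fs / (1 + z^h)`, so
#' the steady state is the root of the scalar residual
#' `z (1 + y(z)^m) - A(x)` on the bracket `[0, A(x)]`. For `m = h = 1` the
#' root is unique (it is the positive root of
#' `z^2 + z (1 + fs - A) - A = 0`) and bisection always converges. For
#' `m * h > 1` multiple stable fixed points can exist; all sign changes on a
#' 400-point scan are refined and the smallest root is returned with
#' `multistable = TRUE`.
#'
#' @param x Dimensionless input value(s), >= 0.
#' @param params A [molecular_params()] object.
#' @param tol Residual tolerance (default `1e-12`).
#' @param max_iter Bisection budget (default 200).
#' @return A tibble with columns `x`, `y`, `z`, `converged`, `residual`,
#'   `multistable`.
#' @examples
#' dnf_steady_state(0, molecular_params(fs = 1)) # z = (sqrt(5) - 1) / 2
#' @export
dnf_steady_state <- function(x, params = molecular_params(),
                             tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(params, "molecular_params"), tol > 0)
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) {
    abort("`x` must be non-negative and non-missing.")
  }
  a <- molecular_activation(x, params)
  sol <- purrr::map(a, dnf_solve_one, params = params,
                    tol = tol, max_iter = max_iter)
  z <- purrr::map_dbl(sol, "z")
  res <- purrr::map_dbl(sol, "residual")
  conv <- purrr::map_lgl(sol, "converged")
  if (!all(conv)) {
    abort(sprintf(
      "DNF fixed-point solver failed to converge (max residual %.3e).",
      max(res[!conv])))
  }
  tibble(x = as.numeric(x),
         y = params$fs / (1 + z^params$h),
         z = z,
         converged = conv,
         residual = res,
         multistable = purrr::map_lgl(sol, "multistable"))
}

#' Closed-form DNF steady state for m = h = 1
#'
#' Independent check of the fixed-point solver: for first-order repression
#' both ways, the steady state is the positive root of the quadratic
#' `z^2 + z (1 + fs - A(x)) - A(x) = 0`.
#'
#' @inheritParams dnf_steady_state
#' @return Numeric vector of output levels `z`.
#' @export
dnf_quadratic_root <- function(x, params = molecular_params()) {
  stopifnot(inherits(params, "molecular_params"))
  if (params$m != 1 || params$h != 1) {
    abort("closed form requires m = 1 and h = 1.")
  }
  a <- molecular_activation(x, params)
  b <- 1 + params$fs - a
  (-b + sqrt(b^2 + 4 * a)) / 2
}

#' Molecular circuit model object
#'
#' Bundles a topology with its parameters for use with
#' [simulate_dose_response()] and [sweep_fs()].
#'
#' @param topology `"ICF"` or `"DNF"`.
#' @param params A [molecular_params()] object.
#' @param tol Residual tolerance for the DNF fixed point.
#' @return An object of class `molecular_circuit`.
#' @examples
#' simulate_dose_response(molecular_circuit("DNF", molecular_params(fs = 1)),
#'                        log_grid(1e-3, 1e3, 5))
#' @export
molecular_circuit <- function(topology = c("ICF", "DNF"),
                              params = molecular_params(), tol = 1e-12) {
  topology <- match.arg(topology)
  stopifnot(inherits(params, "molecular_params"))
  structure(list(topology = topology, params = params, tol = tol),
            class = "molecular_circuit")
}

#' @export
print.molecular_circuit <- function(x, ...) {
  cat(sprintf("<molecular_circuit> %s\n", x$topology))
  print(x$params)
  invisible(x)
}

#' @export
simulate_dose_response.molecular_circuit <- function(model, inputs, ...) {
  inputs <- check_input_grid(inputs)
  ss <- switch(model$topology,
    ICF = icf_steady_state(inputs, model$params),
    DNF = dnf_steady_state(inputs, model$params, tol = model$tol, ...)
  )
  dose_response(inputs, ss$z)
}
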