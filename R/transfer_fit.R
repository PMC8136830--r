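#' Fit a monotone Hill transfer function to dose-response data
#'
#' Fits the four-parameter monotone Hill form
#' \deqn{y = b + a \frac{(d/K_1)^{n_1}}{1 + (d/K_1)^{n_1}}}
#' to measured (or synthetic) responses. Because fluorescence readouts span
#' decades, fitting is done in log space: the objective is the sum of squared
#' residuals of `log10(y)` against `log10(model)`, with positivity bounds on
#' all parameters, `K1` constrained to `[min(dose)/10, max(dose) * 10]` and
#' `n1` to `(0, 6]`. Optimization is bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with a deterministic multistart over `K1`
#' (5 starts, including the dose nearest the half-range response).
#'
#' @param data A data frame of measurements.
#' @param dose,response Column names (unquoted) holding positive doses and
#'   positive responses. Defaults are `dose` and `response`.
#' @param weights Optional per-point weights in log space (default equal).
#' @param model `"hill"` or `"biphasic"` (use [fit_biphasic()] for the
#'   latter; exposed here so both share one engine).
#' @return An object of class `circuit_fit`: estimates `b`, `a`, `K1`, `n1`,
#'   residual sum of squares in log10 space (`sse`), `r2`, and honest
#'   `converged` / `degenerate` flags. Methods: [tidy()], [glance()],
#'   [predict()], [autoplot()].
#' @examples
#' d <- log_grid(0.1, 1000, 12)
#' y <- 0.1 + 0.9 * (d / 10)^1.5 / (1 + (d / 10)^1.5)
#' fit <- fit_hill(tibble::tibble(dose = d, response = y))
#' tidy(fit)
#' @export
fit_hill <- function(data, dose = dose, response = response, weights = NULL,
                     model = "hill") {
  d <- eval_tidy(enquo(dose), data)
  y <- eval_tidy(enquo(response), data)
  fit_transfer(d, y, weights = weights, model = model)
}

#' Fit the biphasic loop-strength response
#'
#' Fits the rise-then-fall form used for metric-versus-AHL curves,
#' \deqn{y = b + a \frac{(d/K_1)^{n_1}}{1 + (d/K_1)^{n_1}} \cdot
#'       \frac{1}{1 + (d/K_1)^{n_1}}
#'     = b + a \frac{u}{(1 + u)^2}, \quad u = (d/K_1)^{n_1},}
#' a Hill activation multiplied by its own complement with shared `K1` and
#' `n1`. The curve is symmetric in log-dose about `K1` and peaks at dose
#' `K1` with value `b + a/4` (see [biphasic_peak()]). Set
#' `independent_arms = TRUE` to allow the falling arm its own constants
#' (`K2`, `n2`); the shared form is the default.
#'
#' @inheritParams fit_hill
#' @param independent_arms If `TRUE`, fit independent `K2`, `n2` for the
#'   repression arm (non-default variant for sensitivity analysis).
#' @return A `circuit_fit` object, as [fit_hill()].
#' @examples
#' d <- log_grid(0.1, 1000, 12)
#' y <- 4 * (d / 10)^2 / (1 + (d / 10)^2)^2
#' fit <- fit_biphasic(tibble::tibble(dose = d, response = y))
#' biphasic_peak(fit)
#' @export
fit_biphasic <- function(data, dose = dose, response = response,
                         weights = NULL, independent_arms = FALSE) {
  d <- eval_tidy(enquo(dose), data)
  y <- eval_tidy(enquo(response), data)
  fit_transfer(d, y, weights = weights,
               model = if (independent_arms) "biphasic2" else "biphasic")
}

transfer_curve <- function(d, par, model) {
  u <- (d / par[["K1"]])^par[["n1"]]
  switch(model,
    hill = par[["b"]] + par[["a"]] * u / (1 + u),
    biphasic = par[["b"]] + par[["a"]] * u / (1 + u)^2,
    biphasic2 = {
      v <- (d / par[["K2"]])^par[["n2"]]
      par[["b"]] + par[["a"]] * u / (1 + u) / (1 + v)
    }
  )
}

fit_transfer <- function(d, y, weights = NULL, model = "hill") {
  if (!model %in% c("hill", "biphasic", "biphasic2")) {
    abort("`model` must be \"hill\", \"biphasic\" or \"biphasic2\".")
  }
  if (anyNA(d) || anyNA(y) || any(d <= 0) || any(y <= 0)) {
    abort("doses and responses must be positive and non-missing.")
  }
  n_par <- if (model == "biphasic2") 6L else 4L
  min_doses <- if (model == "hill") 4L else 5L
  if (length(unique(d)) < min_doses) {
    abort(sprintf("need at least %d distinct doses.", min_doses))
  }
  if (length(d) != length(y)) abort("`dose` and `response` lengths differ.")
  w <- weights %||% rep(1, length(y))

  ly <- log10(y)
  y_rng <- range(y)
  degenerate <- diff(log10(y_rng)) < 1e-8
  if (degenerate) {
    warn("constant response: amplitude is unidentifiable; returning flat fit.")
    est <- c(b = y_rng[1], a = 1e-12 * y_rng[1], K1 = median(d), n1 = 1)
    return(new_circuit_fit(model, est, d, y, sse = 0, converged = FALSE,
                           degenerate = TRUE))
  }

  lo_k <- min(d) / 10
  hi_k <- max(d) * 10
  # dose nearest the half-range response (in log space), plus spread starts
  half <- 10^mean(log10(y_rng))
  k_half <- d[which.min(abs(ly - log10(half)))]
  k_starts <- unique(pmin(hi_k, pmax(lo_k,
    c(k_half, exp(seq(log(min(d)), log(max(d)), length.out = 4))))))

  b0 <- max(min(y), 1e-12)
  a0 <- if (model == "hill") max(diff(y_rng), 1e-12) else 4 * diff(y_rng)

  lower <- c(b = 1e-12, a = 1e-12, K1 = lo_k, n1 = 1e-3)
  upper <- c(b = Inf, a = Inf, K1 = hi_k, n1 = 6)
  if (model == "biphasic2") {
    lower <- c(lower, K2 = lo_k, n2 = 1e-3)
    upper <- c(upper, K2 = hi_k, n2 = 6)
  }

  best <- NULL
  for (k0 in k_starts) {
    start <- c(b = b0, a = a0, K1 = k0, n1 = 1.5)
    if (model == "biphasic2") start <- c(start, K2 = k0, n2 = 1.5)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = function(p) {
          mu <- transfer_curve(d, p, model)
          if (any(mu <= 0) || any(!is.finite(mu))) {
            return(rep(1e6, length(ly)))
          }
          sqrt(w) * (ly - log10(mu))
        },
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    warn("all optimizer starts failed; returning non-converged fit.")
    est <- c(b = b0, a = a0, K1 = k_starts[1], n1 = 1.5)
    if (model == "biphasic2") est <- c(est, K2 = k_starts[1], n2 = 1.5)
    return(new_circuit_fit(model, est, d, y, sse = Inf, converged = FALSE,
                           degenerate = FALSE))
  }
  est <- best$fit$par
  converged <- best$fit$info %in% 1:4
  # model mismatch flags: K1 pinned to a box bound, or, for the biphasic
  # forms, data that the nested monotone Hill model explains at least as
  # well (the falling arm is unsupported, e.g. monotone data).
  suspect <- est[["K1"]] <= lo_k * (1 + 1e-6) ||
    est[["K1"]] >= hi_k * (1 - 1e-6)
  if (model %in% c("biphasic", "biphasic2")) {
    hill_sse <- tryCatch(
      suppressWarnings(fit_transfer(d, y, weights = weights,
                                    model = "hill")$sse),
      error = function(e) Inf)
    suspect <- suspect || hill_sse <= best$sse
  }
  new_circuit_fit(model, est, d, y, sse = best$sse,
                  converged = converged, degenerate = suspect)
}

new_circuit_fit <- function(model, est, d, y, sse, converged, degenerate) {
  mu <- transfer_curve(d, est, model)
  ly <- log10(y)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum((ly - log10(pmax(mu, 1e-300)))^2) / ss_tot else NA_real_
  structure(
    list(model = model, coef = est, data = tibble(dose = d, response = y),
         fitted = mu, sse = sse, r2 = r2, converged = converged,
         degenerate = degenerate),
    class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat(sprintf("<circuit_fit> %s model%s%s\n", x$model,
              if (x$converged) "" else " (NOT converged)",
              if (x$degenerate) " (degenerate)" else ""))
  print(round(x$coef, 6))
  cat(sprintf("sse(log10) = %.4g, r2 = %.4f\n", x$sse, x$r2))
  invisible(x)
}

#' @export
coef.circuit_fit <- function(object, ...) object$coef

#' @export
predict.circuit_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata$dose
  } else {
    newdata
  }
  transfer_curve(d, object$coef, object$model)
}

#' Tidy a transfer-function fit
#'
#' @param x A `circuit_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy circuit_fit
#' @export
tidy.circuit_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of a transfer-function fit
#'
#' @param x A `circuit_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `sse`, `r2`, `converged`, `degenerate`.
#' @method glance circuit_fit
#' @export
glance.circuit_fit <- function(x, ...) {
  tibble(model = x$model, sse = x$sse, r2 = x$r2,
         converged = x$converged, degenerate = x$degenerate)
}

#' @method augment circuit_fit
#' @export
augment.circuit_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted,
                .resid = log10(.data$response) - log10(.data$.fitted))
}

#' Peak of a fitted biphasic response
#'
#' For the shared-constant biphasic form `y = b + a u / (1 + u)^2` with
#' `u = (d/K1)^n1`, the product term is maximal at `u = 1` regardless of
#' `n1`, so the peak sits exactly at dose `K1` with value `b + a/4`.
#'
#' @param fit A `circuit_fit` with `model = "biphasic"`.
#' @return A one-row tibble with `peak_dose` and `peak_value`; a flat fit
#'   (`a` effectively 0) is flagged with a warning and `flat = TRUE`.
#' @examples
#' d <- log_grid(0.1, 1000, 12)
#' y <- 4 * (d / 10)^2 / (1 + (d / 10)^2)^2
#' biphasic_peak(fit_biphasic(tibble::tibble(dose = d, response = y)))
#' @export
biphasic_peak <- function(fit) {
  if (!inherits(fit, "circuit_fit") || fit$model != "biphasic") {
    abort("`fit` must be a circuit_fit with model = \"biphasic\".")
  }
  flat <- fit$coef[["a"]] <= 1e-9 * max(fit$coef[["b"]], 1e-300)
  if (flat) warn("amplitude is ~0; the fitted curve is flat.")
  tibble(peak_dose = fit$coef[["K1"]],
         peak_value = fit$coef[["b"]] + fit$coef[["a"]] / 4,
         flat = flat)
}

#' Bootstrap confidence interval for the fitted K1
#'
#' Resamples the replicate measurements within each dose (with replacement,
#' independently across doses), refits, and returns percentile confidence
#' limits for `K1`. Used to propagate replicate-level measurement noise
#' into the half-effect estimate.
#'
#' @param data A data frame with columns for dose, response and replicate.
#' @param dose,response,replicate Unquoted column names.
#' @param model `"hill"` or `"biphasic"`.
#' @param draws Number of bootstrap draws (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed (explicit; no global state is consumed).
#' @return A one-row tibble with `k1`, `lower`, `upper`, `draws`.
#' @export
bootstrap_k1 <- function(data, dose = dose, response = response,
                         replicate = replicate, model = "hill",
                         draws = 200, level = 0.95, seed = 1) {
  d <- eval_tidy(enquo(dose), data)
  y <- eval_tidy(enquo(response), data)
  r <- eval_tidy(enquo(replicate), data)
  base_fit <- fit_transfer(d, y, model = model)
  by_dose <- split(seq_along(d), d)
  k1s <- withr::with_seed(seed, {
    vapply(seq_len(draws), function(i) {
      idx <- unlist(lapply(by_dose, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      f <- tryCatch(fit_transfer(d[idx], y[idx], model = model),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$coef[["K1"]]
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- quantile(k1s, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(k1 = base_fit$coef[["K1"]], lower = qs[1], upper = qs[2],
         draws = draws)
}
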