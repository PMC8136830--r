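#' Fold-change activation of a dose-response curve
#'
#' FCA is the ratio between the ON state (maximal output) and the OFF state
#' (basal output) of a transfer function. For the monotone curves produced by
#' these circuit models, ON is the output at the largest input and OFF the
#' output at the smallest (`method = "endpoints"`, the default);
#' `method = "extrema"` uses the max/min over the whole curve for
#' non-monotone data. The OFF state is floored at `floor` so that a basal
#' output driven to zero yields a finite, floor-limited FCA.
#'
#' @param data A [dose_response()] tibble (or any data frame with `input`
#'   and `output` columns).
#' @param floor Output floor epsilon applied to the OFF state.
#' @param method `"endpoints"` or `"extrema"`.
#' @return A single number, ON / max(OFF, floor).
#' @examples
#' compute_fca(dose_response(c(1, 10, 100), c(1, 5, 10))) # 10
#' @export
compute_fca <- function(data, floor = 1e-3,
                        method = c("endpoints", "extrema")) {
  data <- as_dose_response(data)
  method <- match.arg(method)
  stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
  if (method == "endpoints") {
    on <- data$output[nrow(data)]
    off <- data$output[1L]
  } else {
    on <- max(data$output)
    off <- min(data$output)
  }
  off <- max(off, floor)
  if (off == 0) abort("OFF state and floor are both zero; FCA is undefined.")
  on / off
}

#' Pointwise logarithmic sensitivity of a dose-response curve
#'
#' The sensitivity at each input is the local logarithmic gain
#' \deqn{S = \frac{dOut/\langle Out\rangle}{dIn/\langle In\rangle}
#'         = \frac{d\,\ln(out)}{d\,\ln(in)},}
#' computed by central differences on the log-log curve (one-sided at the
#' ends). Reading the averages as the local values makes the ratio of
#' relative changes exactly the log-log slope.
#'
#' @param data A [dose_response()] with >= 3 points, positive inputs and
#'   strictly positive outputs.
#' @return A tibble with columns `input` and `sensitivity`.
#' @examples
#' dr <- simulate_dose_response(hill_put(0.1, 1.5), log_grid(1e-3, 1e3, 61))
#' max(sensitivity_curve(dr)$sensitivity)
#' @export
sensitivity_curve <- function(data) {
  data <- as_dose_response(data)
  if (nrow(data) < 3L) abort("need at least 3 points for sensitivity.")
  if (any(data$input <= 0)) abort("`input` values must be positive.")
  if (any(data$output <= 0)) {
    abort("`output` values must be positive (log sensitivity undefined).")
  }
  lx <- log(data$input)
  ly <- log(data$output)
  n <- length(lx)
  s <- numeric(n)
  s[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  s[n] <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    s[i] <- (ly[i + 1] - ly[i - 1]) / (lx[i + 1] - lx[i - 1])
  }
  tibble(input = data$input, sensitivity = s)
}

#' Maximum sensitivity of a curve
#'
#' @inheritParams sensitivity_curve
#' @return The maximum of [sensitivity_curve()] over the grid.
#' @export
max_sensitivity <- function(data) {
  max(sensitivity_curve(data)$sensitivity)
}

#' Minimum detection level (MDL)
#'
#' The MDL is defined as the input level at which the logarithmic
#' sensitivity of the transfer function is maximal — the concentration where
#' the curve responds most strongly in relative terms. Ties are broken
#' toward the smallest input; a flat (constant-output) curve is degenerate
#' and returns the smallest input with a warning.
#'
#' @inheritParams sensitivity_curve
#' @return A single input value from the grid.
#' @examples
#' dr <- simulate_dose_response(hill_put(0.1, 1.5), log_grid(1e-3, 1e3, 601))
#' compute_mdl(dr) # ~ beta^(1 / (2 n)) = 0.464
#' @export
compute_mdl <- function(data) {
  s <- sensitivity_curve(data)
  if (max(s$sensitivity) - min(s$sensitivity) < 1e-14) {
    warn("constant sensitivity curve; MDL is degenerate (smallest input).")
    return(s$input[1L])
  }
  s$input[which.max(s$sensitivity)]
}

#' Switching threshold of a monotone curve
#'
#' The threshold Th is the input at which the output crosses the midpoint
#' between its OFF and ON states on the logarithmic scale, i.e. the
#' geometric mean `sqrt(ON * OFF)`; the crossing is interpolated linearly in
#' log-log space. A curve that never crosses the midpoint (e.g. constant)
#' yields `NA_real_` with a warning.
#'
#' @inheritParams compute_fca
#' @return A single input value (interpolated), or `NA_real_`.
#' @examples
#' dr <- simulate_dose_response(hill_put(0.1, 1.5), log_grid(1e-3, 1e3, 601))
#' compute_threshold(dr) # equals the MDL for the bare Hill PUT
#' @export
compute_threshold <- function(data, floor = 0) {
  data <- as_dose_response(data)
  if (any(data$input <= 0) || any(data$output <= 0)) {
    abort("`input` and `output` must be positive for the log-scale threshold.")
  }
  on <- data$output[nrow(data)]
  off <- max(data$output[1L], floor)
  mid <- sqrt(on * off)
  ly <- log(data$output)
  lmid <- log(mid)
  above <- ly >= lmid
  if (all(above) || !any(above)) {
    warn("curve never crosses the ON/OFF log-midpoint; threshold undefined.")
    return(NA_real_)
  }
  i <- which(above)[1L]
  if (i == 1L) return(data$input[1L])
  lx <- log(data$input)
  frac <- (lmid - ly[i - 1]) / (ly[i] - ly[i - 1])
  exp(lx[i - 1] + frac * (lx[i] - lx[i - 1]))
}

#' All figures of merit for one curve
#'
#' @inheritParams compute_fca
#' @return A one-row tibble with columns `fca`, `s_max`, `mdl`, `threshold`.
#' @examples
#' dr <- simulate_dose_response(hill_put(0.1, 1.5), log_grid(1e-3, 1e3, 201))
#' circuit_metrics(dr)
#' @export
circuit_metrics <- function(data, floor = 1e-3,
                            method = c("endpoints", "extrema")) {
  data <- as_dose_response(data)
  s <- sensitivity_curve(data)
  tibble(
    fca = compute_fca(data, floor = floor, method = method),
    s_max = max(s$sensitivity),
    mdl = s$input[which.max(s$sensitivity)],
    threshold = compute_threshold(data)
  )
}

#' Loop-strength grid
#'
#' Log-spaced grid unless the range includes 0, in which case it is linear.
#'
#' @param from,to Grid end points, `to > from >= 0`.
#' @param n Number of points (default 200).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
fs_grid <- function(from, to, n = 200) {
  stopifnot(to > from, from >= 0, n >= 2)
  if (from <= 0) seq(from, to, length.out = n) else log_grid(from, to, n)
}

#' Sweep the loop strength and record metrics per curve
#'
#' Evaluates a family of dose-response curves indexed by the loop strength
#' `fs` and computes FCA, maximum sensitivity, MDL and threshold for each,
#' mirroring the FCA-versus-loop-strength and MDL-versus-loop-strength
#' analyses the circuit designs are judged by.
#'
#' @param model_factory A function `fs -> model`, where the model is
#'   accepted by [simulate_dose_response()].
#' @param fs Vector of loop strengths to evaluate.
#' @param inputs Input grid for every curve.
#' @param floor Output floor passed to [compute_fca()].
#' @param method ON/OFF convention, see [compute_fca()].
#' @return A tibble of class `fs_sweep` with columns `fs`, `fca`, `s_max`,
#'   `mdl`, `threshold`, carrying `argmax_fca` and `argmin_mdl` attributes
#'   (ties broken toward the smallest `fs`). See [glance.fs_sweep()].
#' @examples
#' sw <- sweep_fs(function(fs) molecular_circuit("ICF", molecular_params(fs = fs)),
#'                fs = c(0, 1, 2), inputs = log_grid(1e-3, 1e3, 101))
#' glance(sw)
#' @export
sweep_fs <- function(model_factory, fs, inputs, floor = 1e-3,
                     method = c("endpoints", "extrema")) {
  stopifnot(is.function(model_factory))
  method <- match.arg(method)
  if (length(fs) == 0L) abort("`fs` grid must be non-empty.")
  rows <- purrr::map(fs, function(f) {
    dr <- simulate_dose_response(model_factory(f), inputs)
    circuit_metrics(dr, floor = floor, method = method)
  })
  out <- dplyr::bind_cols(tibble(fs = as.numeric(fs)), dplyr::bind_rows(rows))
  attr(out, "argmax_fca") <- out$fs[which.max(out$fca)]
  attr(out, "argmin_mdl") <- out$fs[which.min(out$mdl)]
  class(out) <- c("fs_sweep", class(out))
  out
}

#' Summarize a loop-strength sweep
#'
#' @param x An `fs_sweep` from [sweep_fs()].
#' @param ... Unused.
#' @return A one-row tibble with `argmax_fca`, `max_fca`, `argmin_mdl`,
#'   `min_mdl`.
#' @method glance fs_sweep
#' @export
glance.fs_sweep <- function(x, ...) {
  tibble(
    argmax_fca = attr(x, "argmax_fca"),
    max_fca = max(x$fca),
    argmin_mdl = attr(x, "argmin_mdl"),
    min_mdl = min(x$mdl)
  )
}

#' Qualitative basal-level / loop-strength design diagram
#'
#' Classifies each (beta, fs) cell of a linear-circuit design space as
#' FCA-optimal (FCA within a fraction `delta` of the best over `fs` at that
#' beta), MDL-optimal (MDL within `delta` of the best), both, or neither —
#' the qualitative design-space maps used to choose a loop strength for a
#' given promoter basal level.
#'
#' @param topology `"ICF"` or `"DNF"` (linear wirings).
#' @param beta Grid of basal levels in (0, 1).
#' @param fs Grid of loop strengths (for DNF, all < 1).
#' @param delta Tolerance fraction in (0, 1\]; `delta = 1` marks every cell
#'   optimal.
#' @param inputs Input grid for the underlying curves.
#' @param n_put Hill coefficient of the PUT.
#' @param floor Output floor.
#' @return A tibble of class `design_diagram` with columns `beta`, `fs`,
#'   `fca`, `mdl`, `optimal_fca`, `optimal_mdl`, `region`.
#' @examples
#' dd <- design_diagram("DNF", beta = c(0.05, 0.1), fs = seq(0, 0.5, 0.05),
#'                      inputs = log_grid(1e-3, 1e3, 61))
#' head(dd)
#' @export
design_diagram <- function(topology = c("ICF", "DNF"), beta, fs,
                           delta = 0.05, inputs = log_grid(1e-3, 1e3, 201),
                           n_put = 1.5, floor = 1e-3) {
  topology <- match.arg(topology)
  stopifnot(delta > 0, delta <= 1)
  grid <- tidyr::expand_grid(beta = as.numeric(beta), fs = as.numeric(fs))
  cells <- purrr::pmap(grid, function(beta, fs) {
    lc <- linear_circuit(topology, fs = fs, put = hill_put(beta, n_put),
                         floor = floor)
    circuit_metrics(simulate_dose_response(lc, inputs), floor = floor)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  out <- dplyr::group_by(out, .data$beta)
  out <- dplyr::mutate(out,
    optimal_fca = .data$fca >= (1 - delta) * max(.data$fca),
    optimal_mdl = .data$mdl <= (1 + delta) * min(.data$mdl)
  )
  out <- dplyr::ungroup(out)
  out$region <- dplyr::case_when(
    out$optimal_fca & out$optimal_mdl ~ "both",
    out$optimal_fca ~ "optimal-FCA",
    out$optimal_mdl ~ "optimal-MDL",
    TRUE ~ "neither"
  )
  class(out) <- c("design_diagram", class(out))
  out
}
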