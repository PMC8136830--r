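#' Flow-cytometry-style noise model
#'
#' Cytometry fluorescence distributions are close to log-normal and are
#' summarized per well by the geometric mean of the population. The
#' generator draws `n_cells` log-normal per-cell values around the model
#' output, takes their geometric mean, and repeats for each biological
#' replicate; an optional between-replicate log-normal bias models day
#' effects. Defaults follow the measurement design emulated here: 10000
#' events per well and 3 replicates. The per-cell log standard deviation
#' (`log_cv = 0.5`) is a generator choice, not a measured value.
#'
#' @param log_cv Standard deviation of per-cell natural-log fluorescence,
#'   >= 0.
#' @param n_cells Events per well, >= 1 (default 10000).
#' @param replicates Biological replicates, >= 1 (default 3).
#' @param seed RNG seed; every generator call is seeded explicitly and
#'   leaves the global RNG state untouched.
#' @param rep_bias_sd Log-sd of a per-replicate multiplicative bias
#'   (default 0: no day effect).
#' @param autofluorescence Additive background added to every cell
#'   (default 0).
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(log_cv = 0.5, seed = 7)
#' @export
noise_model <- function(log_cv = 0.5, n_cells = 10000, replicates = 3,
                        seed = 1, rep_bias_sd = 0, autofluorescence = 0) {
  stopifnot(
    is.numeric(log_cv), length(log_cv) == 1L, log_cv >= 0,
    is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1,
    is.numeric(replicates), length(replicates) == 1L, replicates >= 1,
    is.numeric(seed), length(seed) == 1L,
    is.numeric(rep_bias_sd), length(rep_bias_sd) == 1L, rep_bias_sd >= 0,
    is.numeric(autofluorescence), length(autofluorescence) == 1L,
    autofluorescence >= 0
  )
  structure(list(log_cv = log_cv, n_cells = as.integer(n_cells),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 rep_bias_sd = rep_bias_sd,
                 autofluorescence = autofluorescence),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> log_cv = %g, n_cells = %d, replicates = %d, seed = %d\n",
    x$log_cv, x$n_cells, x$replicates, x$seed))
  invisible(x)
}

#' Sample one cell population and its geometric mean
#'
#' Draws `n_cells` log-normal values with log-mean `log(mean_level)` and
#' log-sd `log_cv`, and summarizes them by the geometric mean
#' `exp(mean(log(cells)))` — the well-level statistic used throughout.
#'
#' @param mean_level Model output the population fluctuates around, > 0.
#' @param noise A [noise_model()]; its `seed` makes the draw reproducible.
#' @return A list with elements `cells` (numeric vector of length
#'   `n_cells`) and `geomean` (a single number).
#' @examples
#' sample_population(10, noise_model(log_cv = 0.5, n_cells = 100, seed = 3))$geomean
#' @export
sample_population <- function(mean_level, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.numeric(mean_level) || length(mean_level) != 1L ||
      mean_level <= 0 || is.na(mean_level)) {
    abort("`mean_level` must be a single positive number.")
  }
  cells <- withr::with_seed(noise$seed, {
    rlnorm(noise$n_cells, meanlog = log(mean_level), sdlog = noise$log_cv)
  })
  cells <- cells + noise$autofluorescence
  list(cells = cells, geomean = exp(mean(log(cells))))
}

# deterministic model curve evaluation for any supported model argument
model_outputs <- function(model, doses) {
  if (is.function(model)) {
    as.numeric(model(doses))
  } else {
    as_dose_response(simulate_dose_response(model, doses))$output
  }
}

#' Generate a synthetic replicated dose-response experiment
#'
#' Evaluates a circuit model on a dose grid, then emulates the cytometry
#' readout: for each dose and replicate, a log-normal cell population is
#' drawn around the model output and summarized by its geometric mean. The
#' generating model and noise settings travel with the result as ground
#' truth, so recovery can be checked end-to-end.
#'
#' @param model A circuit model accepted by [simulate_dose_response()], or
#'   a function `doses -> outputs`.
#' @param doses Positive, strictly increasing dose grid.
#' @param noise A [noise_model()].
#' @param condition Label for the experiment (default `"circuit"`).
#' @param fs Loop strength recorded alongside (default `NA`).
#' @return A tibble of class `synthetic_experiment` with columns
#'   `condition`, `fs`, `dose`, `replicate`, `geomean`, `n_cells`, `seed`,
#'   and attribute `ground_truth` (list with `model`, `noise`, `outputs`).
#' @examples
#' ex <- generate_experiment(hill_put(0.1, 1.5), log_grid(0.01, 100, 8),
#'                           noise_model(seed = 11))
#' summarize_experiment(ex)
#' @export
generate_experiment <- function(model, doses, noise = noise_model(),
                                condition = "circuit", fs = NA_real_) {
  stopifnot(inherits(noise, "noise_model"))
  doses <- check_input_grid(doses)
  if (any(doses <= 0)) abort("`doses` must be strictly positive.")
  mu <- model_outputs(model, doses)
  if (any(mu <= 0)) {
    abort("model outputs must be positive to sample log-normal populations.")
  }
  grid <- tidyr::expand_grid(dose_i = seq_along(doses),
                             replicate = seq_len(noise$replicates))
  geomeans <- withr::with_seed(noise$seed, {
    rep_bias <- rnorm(noise$replicates, 0, noise$rep_bias_sd)
    purrr::pmap_dbl(grid, function(dose_i, replicate) {
      level <- mu[dose_i] * exp(rep_bias[replicate])
      if (noise$log_cv == 0 && noise$autofluorescence == 0) return(level)
      cells <- rlnorm(noise$n_cells, meanlog = log(level),
                      sdlog = noise$log_cv) + noise$autofluorescence
      exp(mean(log(cells)))
    })
  })
  out <- tibble(
    condition = condition,
    fs = fs,
    dose = doses[grid$dose_i],
    replicate = grid$replicate,
    geomean = geomeans,
    n_cells = noise$n_cells,
    seed = noise$seed
  )
  out <- dplyr::arrange(out, .data$dose, .data$replicate)
  attr(out, "ground_truth") <- list(model = model, noise = noise,
                                    doses = doses, outputs = mu)
  class(out) <- c("synthetic_experiment", class(out))
  out
}

#' Pool replicates of a synthetic (or measured) experiment
#'
#' Per dose: the geometric mean across replicate geometric means, and the
#' standard deviation of the replicate geometric means (the error bars used
#' for such measurements).
#'
#' @param data A data frame with columns `dose`, `replicate`, `geomean`
#'   (and optionally `condition`, `fs`, which are kept as grouping keys).
#' @return A tibble with one row per (condition, fs, dose): `geomean`
#'   (pooled) and `sd_geomean`.
#' @export
summarize_experiment <- function(data) {
  stopifnot(all(c("dose", "geomean") %in% names(data)))
  keys <- intersect(c("condition", "fs", "dose"), names(data))
  out <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(out,
    sd_geomean = sd(.data$geomean),
    geomean = exp(mean(log(.data$geomean))),
    n_replicates = dplyr::n(),
    .groups = "drop")
  dplyr::relocate(out, dplyr::all_of(c(keys, "geomean", "sd_geomean")))
}

#' Convert a pooled experiment to a dose-response curve
#'
#' @param data A `synthetic_experiment` or any data frame with `dose`,
#'   `geomean` (replicates are pooled first if a `replicate` column is
#'   present).
#' @return A [dose_response()] tibble.
#' @export
experiment_dose_response <- function(data) {
  if ("replicate" %in% names(data)) data <- summarize_experiment(data)
  data <- dplyr::arrange(data, .data$dose)
  dose_response(data$dose, data$geomean,
                input_name = "dose", output_name = "geomean")
}

#' Generate a family of experiments across loop strengths
#'
#' Emulates the AHL-titration design in which each loop-strength (AHL)
#' value yields one full dose-response curve: one synthetic experiment is
#' generated per `fs` value, with per-experiment seeds derived
#' deterministically from the base seed.
#'
#' @param model_factory A function `fs -> model`.
#' @param fs_values Loop strengths, >= 0 (an empty vector returns an empty
#'   tibble).
#' @param doses Positive, strictly increasing dose grid.
#' @param noise A [noise_model()]; experiment `i` runs with seed
#'   `noise$seed + 1000 * i`.
#' @param condition Label prefix.
#' @return A tibble of class `ahl_sweep_experiment`: all experiments bound
#'   row-wise, with the `fs` column distinguishing them, and a
#'   `ground_truth` attribute (list of per-fs ground truths).
#' @examples
#' fac <- function(fs) molecular_circuit("ICF", molecular_params(fs = fs))
#' sw <- generate_ahl_sweep(fac, c(0, 1), log_grid(0.01, 100, 6),
#'                          noise_model(n_cells = 100, seed = 5))
#' @export
generate_ahl_sweep <- function(model_factory, fs_values, doses,
                               noise = noise_model(), condition = "circuit") {
  stopifnot(is.function(model_factory))
  if (length(fs_values) == 0L) {
    out <- tibble(condition = character(), fs = numeric(), dose = numeric(),
                  replicate = integer(), geomean = numeric(),
                  n_cells = integer(), seed = integer())
    attr(out, "ground_truth") <- list()
    class(out) <- c("ahl_sweep_experiment", class(out))
    return(out)
  }
  if (any(fs_values < 0)) abort("`fs_values` must be >= 0.")
  exps <- purrr::imap(fs_values, function(f, i) {
    noise_i <- noise
    noise_i$seed <- as.integer(noise$seed + 1000L * i)
    generate_experiment(model_factory(f), doses, noise_i,
                        condition = condition, fs = f)
  })
  out <- dplyr::bind_rows(exps)
  attr(out, "ground_truth") <- purrr::map(exps, attr, "ground_truth")
  class(out) <- c("ahl_sweep_experiment", class(out))
  out
}
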