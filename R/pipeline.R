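#' Read a flat run configuration
#'
#' Run configurations are flat key-value YAML files. Required key:
#' `command` (one of `simulate`, `sweep`, `diagram`, `synth`, `fit`,
#' `recover`). Common keys: `family` (`linear`, `molecular`, `genetic`),
#' `topology` (`OL`/`ICF`/`DNF`), `output_dir`, `seed`, model parameters
#' (`beta`, `alpha`, `n`, `m`, `h`, `fs`, `theta`, `q`, `lambda`, `atc`,
#' `mode`, `floor`), grid settings (`x_min`, `x_max`, `x_n`, `fs_min`,
#' `fs_max`, `fs_n`), noise settings (`log_cv`, `n_cells`, `replicates`)
#' and, for `fit`, `input_csv` and `fit_model` (`hill`/`biphasic`).
#'
#' @param path Path to a YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config file must contain a key-value mapping.")
  structure(cfg, class = "run_config")
}

run_defaults <- list(
  family = "molecular", topology = "ICF", seed = 1,
  beta = 0.1, alpha = 10, n = 1.5, m = 1, h = 1, fs = 0,
  theta = 5, q = 2, lambda = 1, atc = 0, mode = "subtractive",
  floor = 1e-3,
  x_min = 1e-3, x_max = 1e3, x_n = 201,
  fs_min = 0, fs_max = 20, fs_n = 201,
  beta_min = 0.02, beta_max = 0.3, beta_n = 15, delta = 0.05,
  log_cv = 0.5, n_cells = 10000, replicates = 3,
  n_doses = 8, fit_model = "hill", n_trials = 200, k1_tolerance = 0.2,
  output_dir = "."
)

validate_config <- function(config) {
  commands <- c("simulate", "sweep", "diagram", "synth", "fit", "recover")
  if (is.null(config$command) || !config$command %in% commands) {
    abort(paste0("config field `command` must be one of: ",
                 paste(commands, collapse = ", "), "."))
  }
  if (!config$family %in% c("linear", "molecular", "genetic")) {
    abort("config field `family` must be linear, molecular or genetic.")
  }
  if (!config$topology %in% c("OL", "ICF", "DNF")) {
    abort("config field `topology` must be OL, ICF or DNF.")
  }
  if (config$family != "linear" && config$topology == "OL") {
    abort("config field `topology`: OL exists only in the linear family.")
  }
  for (f in c("beta", "alpha", "fs", "floor", "log_cv")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      abort(sprintf("config field `%s` must be a single non-negative number.", f))
    }
  }
  if (config$beta <= 0 || config$beta >= 1) {
    abort("config field `beta` must lie in (0, 1).")
  }
  config
}

config_factory <- function(config) {
  switch(config$family,
    linear = function(fs) {
      linear_circuit(config$topology, fs = fs,
                     put = hill_put(config$beta, config$n),
                     floor = config$floor)
    },
    molecular = function(fs) {
      molecular_circuit(config$topology,
        molecular_params(beta = config$beta, alpha = config$alpha,
                         n = config$n, m = config$m, h = config$h, fs = fs))
    },
    genetic = function(fs) {
      genetic_circuit(config$topology,
        genetic_params(put = hill_put(config$beta, config$n),
                       alpha = config$alpha, theta = config$theta,
                       q = config$q, lambda = config$lambda,
                       atc = config$atc, fs = fs, mode = config$mode,
                       m = config$m, floor = config$floor))
    }
  )
}

run_log <- function(stage, t0, note = "") {
  message(sprintf("[foldgain] %-8s %6.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, note))
}

#' Run a configured analysis pipeline
#'
#' Config-driven driver tying models, sweeps, metrics, fits and the
#' synthetic generator together with file output. Commands:
#'
#' * `simulate` — one dose-response curve + its metrics;
#' * `sweep` — loop-strength sweep (CSV of `fs, fca, s_max, mdl, threshold`
#'   plus a JSON summary);
#' * `diagram` — basal-level / loop-strength design diagram (linear family);
#' * `synth` — synthetic replicated experiment (CSV + ground-truth JSON);
#' * `fit` — fit a Hill or biphasic curve to a dose-response CSV;
#' * `recover` — Monte-Carlo parameter-recovery study (generate, fit,
#'   compare K1 to ground truth across seeds).
#'
#' Every run writes a `manifest.json` (full effective config, seed, package
#' version) sufficient to re-execute it exactly.
#'
#' @param config A path to a YAML config, or a named list / `run_config`.
#' @param overrides Named list overriding config values (analogous to
#'   command-line flags).
#' @return Invisibly, a named list of written file paths plus the main
#'   in-memory result.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' res <- run_pipeline(list(command = "simulate", family = "molecular",
#'                          topology = "ICF", fs = 1, output_dir = dir))
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- modifyList(run_defaults, as.list(config))
  config <- modifyList(config, overrides)
  config <- validate_config(config)
  t0 <- as.numeric(Sys.time())
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(name) file.path(config$output_dir, name)
  factory <- config_factory(config)
  x_grid <- log_grid(config$x_min, config$x_max, config$x_n)
  paths <- list()
  result <- NULL

  if (config$command == "simulate") {
    dr <- simulate_dose_response(factory(config$fs), x_grid)
    metrics <- circuit_metrics(dr, floor = config$floor)
    readr::write_csv(as_tibble(dr), out_path("dose_response.csv"))
    write_metrics_json(metrics, out_path("metrics.json"))
    paths <- list(dose_response = out_path("dose_response.csv"),
                  metrics = out_path("metrics.json"))
    result <- metrics
    run_log("simulate", t0, sprintf("fca = %.4g", metrics$fca))
  } else if (config$command == "sweep") {
    fsg <- fs_grid(config$fs_min, config$fs_max, config$fs_n)
    if (config$family == "linear" && config$topology == "DNF") {
      fsg <- fsg[fsg < 1]
    }
    sw <- sweep_fs(factory, fsg, x_grid, floor = config$floor)
    write_sweep_csv(sw, out_path("sweep.csv"))
    write_metrics_json(glance(sw), out_path("sweep_summary.json"))
    paths <- list(sweep = out_path("sweep.csv"),
                  summary = out_path("sweep_summary.json"))
    result <- sw
    run_log("sweep", t0,
            sprintf("argmax_fca = %.4g", attr(sw, "argmax_fca")))
  } else if (config$command == "diagram") {
    if (config$family != "linear" || config$topology == "OL") {
      abort("`diagram` requires family = linear and topology ICF or DNF.")
    }
    betas <- exp(seq(log(config$beta_min), log(config$beta_max),
                     length.out = config$beta_n))
    fsg <- fs_grid(config$fs_min, config$fs_max, config$fs_n)
    if (config$topology == "DNF") fsg <- fsg[fsg < 1]
    dd <- design_diagram(config$topology, betas, fsg, delta = config$delta,
                         inputs = x_grid, n_put = config$n,
                         floor = config$floor)
    readr::write_csv(as_tibble(dd), out_path("design_diagram.csv"))
    paths <- list(diagram = out_path("design_diagram.csv"))
    result <- dd
    run_log("diagram", t0)
  } else if (config$command == "synth") {
    doses <- log_grid(config$x_min, config$x_max, config$n_doses)
    noise <- noise_model(log_cv = config$log_cv, n_cells = config$n_cells,
                         replicates = config$replicates, seed = config$seed)
    ex <- generate_experiment(factory(config$fs), doses, noise,
                              condition = paste(config$family,
                                                config$topology, sep = "_"),
                              fs = config$fs)
    write_dose_response_csv(ex, out_path("experiment.csv"))
    gt <- attr(ex, "ground_truth")
    jsonlite::write_json(
      list(outputs = gt$outputs, doses = gt$doses,
           log_cv = noise$log_cv, n_cells = noise$n_cells,
           replicates = noise$replicates, seed = noise$seed),
      out_path("ground_truth.json"), digits = NA, pretty = TRUE)
    paths <- list(experiment = out_path("experiment.csv"),
                  ground_truth = out_path("ground_truth.json"))
    result <- ex
    run_log("synth", t0, sprintf("%d wells", nrow(ex)))
  } else if (config$command == "fit") {
    if (is.null(config$input_csv)) {
      abort("config field `input_csv` is required for command = fit.")
    }
    raw <- read_dose_response_csv(config$input_csv)
    pooled <- summarize_experiment(raw)
    fit <- if (config$fit_model == "biphasic") {
      fit_biphasic(pooled, dose = dose, response = geomean)
    } else {
      fit_hill(pooled, dose = dose, response = geomean)
    }
    if (fit$degenerate) warn("fit flagged degenerate; inspect the result.")
    jsonlite::write_json(
      c(as.list(fit$coef),
        list(model = fit$model, sse = fit$sse, r2 = fit$r2,
             converged = fit$converged, degenerate = fit$degenerate)),
      out_path("fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- list(fit = out_path("fit.json"))
    result <- fit
    run_log("fit", t0, sprintf("K1 = %.4g (converged: %s)",
                               fit$coef[["K1"]], fit$converged))
  } else if (config$command == "recover") {
    rec <- recovery_study(
      n_trials = config$n_trials, seed = config$seed,
      model = config$fit_model, log_cv = config$log_cv,
      n_cells = config$n_cells, replicates = config$replicates,
      n_doses = config$n_doses, tolerance = config$k1_tolerance)
    jsonlite::write_json(as.list(rec), out_path("recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- list(recovery = out_path("recovery.json"))
    result <- rec
    run_log("recover", t0, sprintf("recovery rate = %.3f", rec$rate))
  }

  manifest <- list(
    config = config[order(names(config))],
    package_version = as.character(utils::packageVersion("foldgain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$manifest <- out_path("manifest.json")
  invisible(c(paths, list(result = result)))
}

#' Monte-Carlo K1 recovery study
#'
#' Generates `n_trials` synthetic experiments from a known Hill (or
#' biphasic) truth under the cytometry noise model, fits each, and reports
#' the fraction of trials in which the fitted `K1` lands within
#' `tolerance` (relative) of the generating value.
#'
#' @param n_trials Number of seeded trials (default 200).
#' @param seed Base seed; trial `i` uses `seed + i`.
#' @param model `"hill"` or `"biphasic"`.
#' @param true_b,true_a,true_k1,true_n1 Generating parameters.
#' @param log_cv,n_cells,replicates Noise settings (defaults: 0.5 per-cell
#'   log-sd, 10000 cells, 3 replicates).
#' @param n_doses Doses per experiment (default 8, log-spaced over
#'   `[k1/30, 30 k1]`).
#' @param tolerance Relative tolerance on K1 (default 0.2).
#' @return A one-row tibble: `rate` (fraction recovered), `n_trials`,
#'   `median_rel_err` and the generating parameters.
#' @export
recovery_study <- function(n_trials = 200, seed = 1, model = "hill",
                           true_b = 0.1, true_a = 0.9, true_k1 = 10,
                           true_n1 = 1.5, log_cv = 0.5, n_cells = 10000,
                           replicates = 3, n_doses = 8, tolerance = 0.2) {
  doses <- log_grid(true_k1 / 30, true_k1 * 30, n_doses)
  truth <- function(d) {
    transfer_curve(d, c(b = true_b, a = true_a, K1 = true_k1, n1 = true_n1),
                   model)
  }
  k1_hat <- vapply(seq_len(n_trials), function(i) {
    noise <- noise_model(log_cv = log_cv, n_cells = n_cells,
                         replicates = replicates, seed = seed + i)
    ex <- generate_experiment(truth, doses, noise)
    pooled <- summarize_experiment(ex)
    fit <- tryCatch(
      fit_transfer(pooled$dose, pooled$geomean, model = model),
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$coef[["K1"]]
  }, numeric(1))
  rel_err <- abs(k1_hat - true_k1) / true_k1
  tibble(
    rate = mean(!is.na(rel_err) & rel_err <= tolerance),
    n_trials = n_trials,
    median_rel_err = median(rel_err, na.rm = TRUE),
    true_k1 = true_k1, model = model,
    log_cv = log_cv, n_cells = n_cells, replicates = replicates
  )
}
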