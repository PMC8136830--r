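test_that("population sampling is seeded, exact at zero noise, and unbiased", {
  # zero noise: every cell equals the mean level
  n0 <- noise_model(log_cv = 0, n_cells = 50, seed = 1)
  s0 <- sample_population(7, n0)
  expect_equal(s0$cells, rep(7, 50))
  expect_equal(s0$geomean, 7)
  # same seed twice: bitwise identical
  n1 <- noise_model(log_cv = 0.5, n_cells = 1000, seed = 42)
  expect_identical(sample_population(10, n1), sample_population(10, n1))
  # different seed differs
  n2 <- noise_model(log_cv = 0.5, n_cells = 1000, seed = 43)
  expect_false(identical(sample_population(10, n1)$geomean,
                         sample_population(10, n2)$geomean))
  # CLT bound on the log of the geometric mean: 3 sigma / sqrt(n)
  n3 <- noise_model(log_cv = 0.5, n_cells = 10000, seed = 7)
  g <- sample_population(10, n3)$geomean
  expect_lt(abs(log(g) - log(10)), 3 * 0.5 / sqrt(10000))
  expect_error(sample_population(0, n3), "positive")
})

test_that("generated experiments have the right shape and embedded truth", {
  doses <- log_grid(0.01, 100, 8)
  noise <- noise_model(log_cv = 0.5, n_cells = 200, replicates = 3, seed = 9)
  ex <- generate_experiment(hill_put(0.1, 1.5), doses, noise,
                            condition = "put", fs = 0.5)
  expect_s3_class(ex, "synthetic_experiment")
  expect_equal(nrow(ex), 8 * 3)
  expect_named(ex, c("condition", "fs", "dose", "replicate", "geomean",
                     "n_cells", "seed"))
  gt <- attr(ex, "ground_truth")
  expect_equal(gt$outputs, put_transfer(doses, hill_put(0.1, 1.5)))
  # determinism of the full experiment
  ex2 <- generate_experiment(hill_put(0.1, 1.5), doses, noise,
                             condition = "put", fs = 0.5)
  expect_identical(ex$geomean, ex2$geomean)
})

test_that("zero-noise experiments reproduce the model curve exactly", {
  doses <- log_grid(0.01, 100, 6)
  noise <- noise_model(log_cv = 0, n_cells = 10, replicates = 2, seed = 1)
  mc <- molecular_circuit("ICF", molecular_params(fs = 1))
  ex <- generate_experiment(mc, doses, noise)
  truth <- simulate_dose_response(mc, doses)
  # per-well values are exact; pooling adds only log/exp round-off
  expect_identical(unique(ex$geomean), truth$output)
  expect_equal(summarize_experiment(ex)$geomean, truth$output,
               tolerance = 1e-12)
})

test_that("end-to-end: measured FCA of the bare circuit is close to 1/beta", {
  doses <- log_grid(1e-3, 1e3, 8)
  ex <- generate_experiment(
    molecular_circuit("ICF", molecular_params(fs = 0)), doses,
    noise_model(seed = 5))
  fca <- compute_fca(experiment_dose_response(ex), floor = 0)
  # replicate noise on the geometric mean of 10000 cells is ~0.5% per well
  expect_equal(fca, 10, tolerance = 0.05)
})

test_that("pooled summaries match hand-computed geometric means", {
  toy <- tibble::tibble(
    condition = "c", fs = 0,
    dose = rep(c(1, 10), each = 2),
    replicate = rep(1:2, 2),
    geomean = c(2, 8, 10, 40),
    n_cells = 10L, seed = 1L
  )
  pooled <- summarize_experiment(toy)
  expect_equal(pooled$geomean, c(4, 20)) # exp(mean(log)) per dose
  expect_equal(pooled$sd_geomean, c(sd(c(2, 8)), sd(c(10, 40))))
})

test_that("replicate bias adds between-replicate variability", {
  doses <- log_grid(0.1, 10, 4)
  noise <- noise_model(log_cv = 0, replicates = 3, seed = 2,
                       rep_bias_sd = 0.3)
  ex <- generate_experiment(function(d) rep(10, length(d)), doses, noise)
  per_rep <- tapply(ex$geomean, ex$replicate, unique)
  expect_equal(length(unique(unlist(per_rep))), 3) # one level per replicate
})

test_that("AHL sweeps stack per-fs experiments with derived seeds", {
  fac <- function(fs) linear_circuit("DNF", fs, hill_put(0.1, 1.5),
                                     floor = 1e-3)
  doses <- log_grid(1e-3, 1e3, 6)
  sw <- generate_ahl_sweep(fac, c(0, 0.05, 0.1, 0.3), doses,
                           noise_model(log_cv = 0, n_cells = 10,
                                       replicates = 2, seed = 11))
  expect_s3_class(sw, "ahl_sweep_experiment")
  expect_equal(nrow(sw), 4 * 6 * 2)
  expect_equal(unique(sw$fs), c(0, 0.05, 0.1, 0.3))
  expect_equal(length(attr(sw, "ground_truth")), 4)
  # noiseless FCA rises then plateaus at the floor-limited value at fs = beta
  fca <- vapply(split(sw, sw$fs), function(d) {
    compute_fca(experiment_dose_response(d), floor = 1e-3)
  }, numeric(1))
  # rises to the floor-limited plateau (flat up to finite-grid round-off)
  expect_true(all(diff(fca) >= -1e-3 * fca[-length(fca)]))
  expect_equal(unname(fca[3]), 1000, tolerance = 1e-3) # fs = beta = 0.1
  # empty sweep
  empty <- generate_ahl_sweep(fac, numeric(0), doses, noise_model())
  expect_equal(nrow(empty), 0)
})

test_that("biphasic FCA-vs-fs profile of the molecular DNF survives generation", {
  fac <- function(fs) molecular_circuit("DNF", molecular_params(fs = fs))
  fs_vals <- c(0, 2, 4, 6.5, 10, 15, 20)
  doses <- log_grid(1e-3, 1e3, 12)
  sw <- generate_ahl_sweep(fac, fs_vals, doses,
                           noise_model(log_cv = 0, n_cells = 10,
                                       replicates = 2, seed = 3))
  fca <- vapply(split(sw, sw$fs), function(d) {
    compute_fca(experiment_dose_response(d), floor = 0)
  }, numeric(1))
  expect_equal(unname(which.max(fca)), 4) # interior peak near fs = 6.5
  expect_gt(max(fca), fca[1])
  expect_gt(max(fca), fca[length(fca)])
})
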