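test_that("FCA follows the endpoint convention with floor handling", {
  dr <- dose_response(c(1, 10, 100), c(1, 5.5, 10))
  expect_equal(compute_fca(dr), 10)
  # constant curve
  expect_equal(compute_fca(dose_response(1:3, rep(2, 3))), 1)
  # OFF below the floor
  dr0 <- dose_response(c(1, 10), c(0, 1))
  expect_equal(compute_fca(dr0, floor = 1e-3), 1000)
  expect_error(compute_fca(dr0, floor = 0), "undefined")
  # extrema mode for non-monotone curves
  hump <- dose_response(c(1, 10, 100), c(2, 8, 4))
  expect_equal(compute_fca(hump, method = "extrema"), 4)
  expect_equal(compute_fca(hump, method = "endpoints"), 2)
})

test_that("FCA is invariant under uniform output rescaling", {
  dr <- simulate_dose_response(default_put, x_grid_201)
  scaled <- dose_response(dr$input, dr$output * 137)
  expect_equal(compute_fca(dr, floor = 0), compute_fca(scaled, floor = 0))
})

test_that("log-log sensitivity recovers power laws and flat curves", {
  x <- log_grid(1e-2, 1e2, 51)
  expect_equal(sensitivity_curve(dose_response(x, rep(3, 51)))$sensitivity,
               rep(0, 51))
  expect_equal(sensitivity_curve(dose_response(x, x))$sensitivity,
               rep(1, 51), tolerance = 1e-10)
  for (k in c(0.5, 2.7)) {
    s <- sensitivity_curve(dose_response(x, 5 * x^k))$sensitivity
    expect_equal(s, rep(k, 51), tolerance = 1e-8)
  }
  expect_error(sensitivity_curve(dose_response(x[1:2], c(1, 2))), "3 points")
  expect_error(sensitivity_curve(dose_response(x, c(0, rep(1, 50)))),
               "positive")
})

test_that("bare-PUT max sensitivity and MDL match the closed forms", {
  dr <- simulate_dose_response(default_put, x_grid_601)
  s_max <- max_sensitivity(dr)
  expect_equal(s_max, put_smax_exact(0.1, 1.5), tolerance = 0.01)
  mdl <- compute_mdl(dr)
  grid_step <- (1e3 / 1e-3)^(1 / 600)
  expect_lt(abs(log(mdl / put_mdl_exact(0.1, 1.5))), log(grid_step) + 1e-12)
})

test_that("threshold is the log-midpoint crossing and equals MDL for the PUT", {
  dr <- simulate_dose_response(default_put, x_grid_601)
  th <- compute_threshold(dr)
  # closed form: p(u) = sqrt(beta) at u^n = sqrt(beta)
  expect_equal(th, 0.1^(1 / 3), tolerance = 1e-3)
  # MDL and threshold coincide for the bare PUT (within one grid step)
  grid_step <- (1e3 / 1e-3)^(1 / 600)
  expect_lt(abs(log(th / compute_mdl(dr))), log(grid_step) + 1e-12)
  # two-point step curve: interpolated midpoint
  step_dr <- dose_response(c(1, 100), c(1, 100))
  expect_equal(compute_threshold(step_dr), 10)
  # curve that never crosses: flagged sentinel
  expect_warning(res <- compute_threshold(dose_response(1:3, rep(1, 3))),
                 "midpoint")
  expect_true(is.na(res))
})

test_that("degenerate MDL is flagged and tie-broken to the smallest input", {
  expect_warning(mdl <- compute_mdl(dose_response(c(1, 10, 100), rep(2, 3))),
                 "degenerate")
  expect_equal(mdl, 1)
})

test_that("sweep records per-fs metrics with smallest-fs tie-breaks", {
  sw <- sweep_fs(
    function(fs) molecular_circuit("ICF", molecular_params(fs = fs)),
    fs = c(0, 1, 2, 5), inputs = x_grid_201, floor = 0)
  expect_s3_class(sw, "fs_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$fca) > 0)) # monotone for molecular ICF
  expect_equal(attr(sw, "argmax_fca"), 5)
  g <- glance(sw)
  expect_named(g, c("argmax_fca", "max_fca", "argmin_mdl", "min_mdl"))
  expect_error(sweep_fs(function(f) molecular_circuit("ICF"),
                        numeric(0), x_grid_201), "non-empty")
})

test_that("linear DNF FCA plateaus at 1/floor beyond fs = beta", {
  sw <- sweep_fs(
    function(fs) linear_circuit("DNF", fs, hill_put(0.1, 1.5), floor = 1e-3),
    fs = seq(0, 0.5, by = 0.02), inputs = x_grid_201, floor = 1e-3)
  expect_equal(sw$fca[sw$fs >= 0.1], rep(1000, sum(sw$fs >= 0.1)),
               tolerance = 1e-3)
  expect_true(all(diff(sw$fca[sw$fs <= 0.1]) >= 0))
})

test_that("max sensitivities of the three wirings agree at matched sub-optimal fs", {
  beta <- 0.1
  put <- hill_put(beta, 1.5)
  s <- c(
    OL  = max_sensitivity(simulate_dose_response(
      linear_circuit("OL", 0.5 * beta, put, floor = 0), x_grid_201)),
    ICF = max_sensitivity(simulate_dose_response(
      linear_circuit("ICF", 0.5 * beta / (1 - beta), put, floor = 0),
      x_grid_201)),
    DNF = max_sensitivity(simulate_dose_response(
      linear_circuit("DNF", 0.5 * beta, put, floor = 0), x_grid_201))
  )
  expect_lt(diff(range(s)) / min(s), 0.02)
})

test_that("design diagram boundaries track the optimal-fs formulas", {
  betas <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  fs_icf <- seq(0.005, 0.6, by = 0.005)
  dd <- design_diagram("ICF", betas, fs_icf, delta = 0.05,
                       inputs = x_grid_201)
  for (b in betas) {
    cells <- dd[dd$beta == b & dd$optimal_fca, ]
    # smallest FCA-optimal fs sits at the formula within grid resolution
    expect_lt(abs(min(cells$fs) - b / (1 - b)), 0.005 + 1e-12)
  }
  fs_dnf <- seq(0.005, 0.6, by = 0.005)
  dd2 <- design_diagram("DNF", betas, fs_dnf, delta = 0.05,
                        inputs = x_grid_201)
  for (b in betas) {
    cells <- dd2[dd2$beta == b & dd2$optimal_fca, ]
    expect_lt(abs(min(cells$fs) - b), 0.005 + 1e-12)
  }
  # degenerate tolerance marks everything optimal
  dd3 <- design_diagram("ICF", 0.1, c(0.05, 0.2), delta = 1,
                        inputs = x_grid_201)
  expect_true(all(dd3$optimal_fca) && all(dd3$optimal_mdl))
})

test_that("fs_grid is log-spaced away from zero and linear across it", {
  g1 <- fs_grid(0.01, 10, 5)
  expect_equal(diff(log(g1)), rep(diff(log(g1))[1], 4), tolerance = 1e-12)
  g2 <- fs_grid(0, 10, 5)
  expect_equal(g2, seq(0, 10, length.out = 5))
})
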