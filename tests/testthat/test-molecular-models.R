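test_that("ICF steady state matches direct substitution into the equations", {
  # no loop: basal output alpha * beta
  s0 <- icf_steady_state(0, molecular_params(fs = 0))
  expect_equal(s0$y, 0)
  expect_equal(s0$z, 1)
  # fs = 1, x = 0: y = 1, z = alpha * beta / 2
  s1 <- icf_steady_state(0, molecular_params(fs = 1))
  expect_equal(s1$y, 1)
  expect_equal(s1$z, 0.5)
  # fs = 1, x = 1: y = 1/2, z = 10 * 0.55 / 1.5
  s2 <- icf_steady_state(1, molecular_params(fs = 1))
  expect_equal(s2$y, 0.5)
  expect_equal(s2$z, 10 * 0.55 / 1.5)
})

test_that("DNF solver matches the quadratic closed form and bisection oracle", {
  xs <- log_grid(1e-3, 1e3, 25)
  for (fs in c(0, 0.5, 1, 5, 20)) {
    params <- molecular_params(fs = fs)
    ss <- dnf_steady_state(xs, params)
    expect_true(all(ss$converged))
    expect_lt(max(abs(ss$z - dnf_quadratic_root(xs, params))), 1e-10)
  }
  # independent bisection oracle at spot values
  params <- molecular_params(fs = 1)
  expect_equal(dnf_steady_state(0, params)$z, bisect_dnf_z(0, params),
               tolerance = 1e-9)
  expect_equal(dnf_steady_state(1e6, params)$z, bisect_dnf_z(1e6, params),
               tolerance = 1e-9)
})

test_that("DNF closed-form landmarks: golden-ratio basal and saturated output", {
  params <- molecular_params(fs = 1)
  expect_equal(dnf_steady_state(0, params)$z, (sqrt(5) - 1) / 2,
               tolerance = 1e-10)
  expect_equal(dnf_steady_state(1e6, params)$z, (8 + sqrt(104)) / 2 - 0,
               tolerance = 1e-3) # A -> 10 limit, evaluated at x = 1e6
  expect_equal(dnf_steady_state(1e6, params)$z,
               dnf_quadratic_root(1e6, params), tolerance = 1e-12)
})

test_that("fs = 0 reduces both topologies to the bare PUT scaled by alpha", {
  params <- molecular_params(fs = 0)
  xs <- log_grid(1e-3, 1e3, 41)
  icf <- icf_steady_state(xs, params)
  dnf <- dnf_steady_state(xs, params)
  expect_equal(icf$z, dnf$z, tolerance = 1e-10)
  expect_equal(icf$z, 10 * put_transfer(xs, hill_put(0.1, 1.5)),
               tolerance = 1e-12)
  # FCA = 1/beta exactly in the wide-grid limit
  dr <- simulate_dose_response(molecular_circuit("ICF", params),
                               log_grid(1e-6, 1e6, 101))
  expect_equal(compute_fca(dr, floor = 0), 1 / 0.1, tolerance = 1e-6)
})

test_that("ICF FCA follows (1 + fs)/beta and rises monotonically with fs", {
  wide <- log_grid(1e-5, 1e5, 201)
  fs_vals <- seq(0, 20, length.out = 41)
  fca <- vapply(fs_vals, function(f) {
    dr <- simulate_dose_response(
      molecular_circuit("ICF", molecular_params(fs = f)), wide)
    compute_fca(dr, floor = 0)
  }, numeric(1))
  expect_equal(fca, (1 + fs_vals) / 0.1, tolerance = 1e-4)
  expect_true(all(diff(fca) > 0))
})

test_that("ICF MDL is non-decreasing in fs", {
  mdl <- vapply(c(0, 0.5, 1, 2, 5, 10), function(f) {
    compute_mdl(simulate_dose_response(
      molecular_circuit("ICF", molecular_params(fs = f)), x_grid_601))
  }, numeric(1))
  expect_true(all(diff(mdl) >= 0))
  expect_gte(mdl[3], mdl[1]) # MDL(fs = 1) >= MDL(fs = 0)
})

test_that("DNF FCA has an interior maximum in the stated window", {
  sw <- sweep_fs(
    function(fs) molecular_circuit("DNF", molecular_params(fs = fs)),
    fs = seq(0, 20, length.out = 201), inputs = x_grid_201, floor = 0)
  g <- glance(sw)
  expect_gt(g$argmax_fca, 5)
  expect_lt(g$argmax_fca, 8)
  expect_gt(g$max_fca, 30.5)
  expect_lt(g$max_fca, 31.5)
  # interior: strictly above both ends
  expect_gt(g$max_fca, sw$fca[1])
  expect_gt(g$max_fca, sw$fca[nrow(sw)])
})

test_that("dose-response vectorization is consistent with scalar calls", {
  params <- molecular_params(fs = 1)
  dr <- simulate_dose_response(molecular_circuit("DNF", params), 1)
  expect_equal(dr$output, dnf_steady_state(1, params)$z)
  dr2 <- simulate_dose_response(molecular_circuit("ICF", molecular_params()),
                                log_grid(1e-3, 1e3, 9))
  expect_equal(dr2$output[1], 1, tolerance = 1e-3)   # alpha * beta limit
  expect_equal(dr2$output[9], 10, tolerance = 1e-3)  # alpha limit
  expect_error(simulate_dose_response(molecular_circuit("ICF"), numeric(0)),
               "non-empty")
  expect_error(simulate_dose_response(molecular_circuit("ICF"), c(1, 1)),
               "increasing")
})

test_that("multistability scan flags coexisting DNF fixed points", {
  # strong mutual repression (m h > 1) can be bistable; the solver must
  # report the smallest root and flag it rather than silently pick one
  params <- molecular_params(beta = 0.01, alpha = 100, n = 1.5,
                             m = 4, h = 4, fs = 30)
  ss <- dnf_steady_state(c(0.5, 1), params)
  expect_true(all(ss$converged))
  expect_true(all(ss$residual < 1e-8))
  # at least verify each reported z really is a fixed point
  y <- params$fs / (1 + ss$z^params$h)
  a <- 100 * (c(0.5, 1)^1.5 + 0.01) / (1 + c(0.5, 1)^1.5)
  expect_equal(ss$z * (1 + y^params$m), a, tolerance = 1e-6)
})
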