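# shared fixtures: reference parameter sets and grids used across tests

default_put <- hill_put(beta = 0.1, n = 1.5)
x_grid_201 <- log_grid(1e-3, 1e3, 201)
x_grid_601 <- log_grid(1e-3, 1e3, 601)

# closed-form figures of merit for the bare Hill PUT:
# max log-sensitivity n (1 - sqrt(beta)) / (1 + sqrt(beta)), attained at
# u = beta^(1 / (2 n)), which is also the log-midpoint threshold.
put_smax_exact <- function(beta, n) n * (1 - sqrt(beta)) / (1 + sqrt(beta))
put_mdl_exact <- function(beta, n) beta^(1 / (2 * n))

# brute-force FCA-optimal loop strength for a linear circuit: grid search
# over fs with a vanishing floor (independent of linear_optimal_fs)
grid_search_optimal_fs <- function(topology, beta, step = 1e-4, eps = 1e-9) {
  hi <- if (topology == "ICF") 0.6 else 0.5
  fs <- seq(0, hi, by = step)
  if (topology == "DNF") fs <- fs[fs < 1]
  put <- hill_put(beta, 1.5)
  fca <- vapply(fs, function(f) {
    lc <- linear_circuit(topology, f, put, floor = eps)
    linear_response(1, lc) / linear_response(beta, lc)
  }, numeric(1))
  fs[which.max(fca)]
}

# independent bisection oracle for the molecular DNF fixed point
bisect_dnf_z <- function(x, params, tol = 1e-13) {
  a <- params$alpha * (x^params$n + params$beta) / (1 + x^params$n)
  f <- function(z) z * (1 + (params$fs / (1 + z^params$h))^params$m) - a
  lo <- 0; hi <- a
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# hand-computed four-node ICF reference (subtractive mode):
# beta=0.1, n=1.5, alpha=10, theta=5, q=2, lambda=1, atc=0, fs=2, x=0
genetic_icf_hand <- list(p = 0.1, t = 0.5, L = 0.8, w = 1.6, z = 1e-3)
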