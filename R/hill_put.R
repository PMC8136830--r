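#' Promoter-under-test transfer function
#'
#' A normalized promoter (or "part under test", PUT) is described by two
#' distinct activity levels: a basal level `beta` in (0, 1) reached with no
#' stimulus (leaky expression from unspecific RNA-polymerase binding) and a
#' maximal level normalized to 1. The transfer function interpolating between
#' them is the saturating Hill form
#' \deqn{p(u) = \frac{u^n + \beta}{1 + u^n}}
#' which is monotone non-decreasing with \eqn{p(0) = \beta} and
#' \eqn{p(u) \to 1} as \eqn{u \to \infty}. Any function with those properties
#' can stand in for a PUT; circuit constructors accept a custom `transfer`
#' function as long as it respects the same bounds.
#'
#' @param beta Basal (OFF-state) activity, dimensionless, in (0, 1).
#' @param n Hill coefficient of activation, > 0.
#'
#' @return An object of class `hill_put`: a list with elements `beta` and `n`.
#' @examples
#' put <- hill_put(beta = 0.1, n = 1.5)
#' put_transfer(c(0, 1, 1e6), put)
#' @export
hill_put <- function(beta = 0.1, n = 1.5) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    abort("`beta` must be a single number in (0, 1).")
  }
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    abort("`n` must be a single positive number.")
  }
  structure(list(beta = beta, n = n), class = "hill_put")
}

#' @export
print.hill_put <- function(x, ...) {
  cat(sprintf("<hill_put> beta = %g, n = %g\n", x$beta, x$n))
  invisible(x)
}

#' Evaluate a PUT transfer function
#'
#' @param u Dimensionless input level(s), >= 0.
#' @param put A [hill_put()] object.
#' @return Numeric vector of PUT activities in \[beta, 1\].
#' @examples
#' put_transfer(1, hill_put(0.1, 1.5)) # (1 + 0.1) / 2 = 0.55
#' @export
put_transfer <- function(u, put = hill_put()) {
  stopifnot(inherits(put, "hill_put"))
  if (!is.numeric(u) || any(u < 0) || anyNA(u)) {
    abort("`u` must be non-negative and non-missing.")
  }
  un <- u^put$n
  (un + put$beta) / (1 + un)
}
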