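#' Conditional non-detection probability under Poisson abundance
#'
#' Probability of detecting no individual in any of `n` randomly placed
#' quadrats, conditional on the species being present somewhere in the area
#' (`Y > 0`), when per-quadrat counts are independent Poisson(`lambda`) and
#' each present individual is independently missed with probability `delta`:
#'
#' \deqn{p = \frac{e^{-\lambda n (1-\delta)} - e^{-\lambda N}}{1 - e^{-\lambda N}}}
#'
#' With `area_size = Inf` the conditioning event has probability one and the
#' expression degenerates to \eqn{e^{-\lambda n (1-\delta)}}.
#'
#' @param lambda Mean number of individuals per quadrat (Poisson rate).
#' @param area_size Total number of quadrats `N` in the area; a positive
#'   integer or `Inf`.
#' @param n Number of quadrats sampled, `1 <= n <= N`.
#' @param delta Per-individual false-negative probability in `[0, 1)`.
#' @return A single probability in `[0, 1)`.
#' @examples
#' nondetect_prob(0.001, 3000, 2330)   # just under 0.05
#' nondetect_prob(0.01, 300, 300)      # 0: the whole area was sampled
#' @seealso [n_poisson()] for the minimum `n` meeting a target bound.
#' @export
nondetect_prob <- function(lambda, area_size, n, delta = 0) {
  check_lambda(lambda)
  check_area_size(area_size)
  check_delta(delta)
  check_n_samples(n, area_size)
  top <- exp(-lambda * n * (1 - delta))
  if (is.infinite(area_size)) {
    return(top)
  }
  e_N <- exp(-lambda * area_size)
  # n = N with delta = 0 gives exactly 0; guard the subtraction
  max(0, (top - e_N) / (1 - e_N))
}

#' Minimum number of quadrats under the Poisson abundance model
#'
#' Smallest integer `n` such that the probability of failing to detect the
#' species from `n` random quadrats, given that it is present in the area,
#' does not exceed `beta`. Per-quadrat counts are independent
#' Poisson(`lambda`); each individual is missed independently with
#' probability `delta`. The closed forms are
#'
#' \deqn{n = \left\lceil -\frac{1}{\lambda(1-\delta)}
#'   \log\left(\beta + (1-\beta) e^{-\lambda N}\right) \right\rceil}
#'
#' for a finite area of `N` quadrats, and
#' \eqn{n = \lceil -\log(\beta) / (\lambda(1-\delta)) \rceil} as
#' \eqn{N \to \infty}. Ignoring a known finite `N` always overestimates `n`
#' (see [overestimation_bound()]); ignoring a real `delta > 0`
#' underestimates it.
#'
#' The returned ceiling is verified against the defining inequality
#' `nondetect_prob(lambda, area_size, n, delta) <= beta` so floating-point
#' noise cannot shift the integer answer. With `delta = 0` the result is
#' guaranteed to satisfy `1 <= n <= N`; with `delta > 0` it can exceed a
#' finite `N`, in which case it is returned uncapped (no `n <= N` can meet
#' the bound) — [recommend_n()] reports such designs as infeasible.
#'
#' @inheritParams nondetect_prob
#' @param beta Maximum tolerated conditional non-detection probability,
#'   in `(0, 1)`.
#' @return A single positive integer.
#' @examples
#' n_poisson(0.05, 0.001)                 # 2996, infinite-area answer
#' n_poisson(0.05, 0.001, 3000)           # 2330: knowing N saves 666 samples
#' n_poisson(0.05, 0.001, 3500, 0.1)      # 2825: detection error costs samples
#' @export
n_poisson <- function(beta, lambda, area_size = Inf, delta = 0) {
  check_beta(beta)
  check_lambda(lambda)
  check_area_size(area_size)
  check_delta(delta)
  if (is.infinite(area_size)) {
    x <- -log(beta) / (lambda * (1 - delta))
    ok <- function(m) exp(-lambda * m * (1 - delta)) <= beta
    return(verified_ceiling(x, ok))
  }
  x <- -log(beta + (1 - beta) * exp(-lambda * area_size)) /
    (lambda * (1 - delta))
  ok <- NULL
  if (ceiling(x) <= area_size) {
    ok <- function(m) nondetect_prob(lambda, area_size, m, delta) <= beta
  }
  verified_ceiling(x, ok)
}

#' Upper bound on the overestimation from assuming an infinite area
#'
#' Cost, in quadrats, of using the infinite-area formula when the area is
#' known to hold only `N` quadrats: the difference between the infinite-area
#' and finite-area minimum sample sizes is between 0 and
#'
#' \deqn{\left\lceil \frac{1}{\lambda(1-\delta)}
#'   \log\left(1 + \frac{1-\beta}{\beta} e^{-\lambda N}\right) \right\rceil}
#'
#' and equals this bound minus one once `N` is large enough.
#'
#' @inheritParams n_poisson
#' @return A single non-negative integer.
#' @examples
#' overestimation_bound(0.05, 0.001, 3000)            # 666
#' n_poisson(0.05, 0.001) - n_poisson(0.05, 0.001, 3000)
#' @export
overestimation_bound <- function(beta, lambda, area_size, delta = 0) {
  check_beta(beta)
  check_lambda(lambda)
  check_area_size(area_size)
  check_delta(delta)
  if (is.infinite(area_size)) {
    return(0L)
  }
  x <- log1p((1 - beta) / beta * exp(-lambda * area_size)) /
    (lambda * (1 - delta))
  max(0L, as.integer(ceiling(x - 1e-12)))
}
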