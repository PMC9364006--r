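#' Negative Binomial parameter set for overdispersed quadrat counts
#'
#' The package parameterizes the Negative Binomial by its size `r` and mean
#' `lambda` (per quadrat), the parameterization preferred for estimation.
#' The usual success parameter is `p = lambda / (r + lambda)`, the variance
#' is `lambda * (1 + lambda / r) > lambda`, and the variance-to-mean ratio
#' `1 + lambda / r` is the dispersion index (1 for the Poisson). The NB also
#' carries zero inflation: its zero mass `(1 + lambda/r)^(-r)` exceeds the
#' Poisson's `exp(-lambda)` for every finite `r` and decreases to it as
#' `r` grows.
#'
#' @param r Positive size parameter(s). Any positive real is accepted; the
#'   closed forms and the moment estimator are well defined for non-integer
#'   `r`.
#' @param lambda Positive mean count(s) per quadrat; recycled against `r`.
#' @return A tibble with one row per `(r, lambda)` pair and columns `r`,
#'   `lambda`, `p`, `dispersion_index`, `zero_mass`.
#' @examples
#' negbin_params(r = 2, lambda = 1)  # dispersion index 1.5
#' @export
negbin_params <- function(r, lambda) {
  if (!is.numeric(r) || length(r) == 0 || anyNA(r) || any(r <= 0)) {
    stop("`r` must be positive.", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) == 0 || anyNA(lambda) ||
      any(lambda <= 0)) {
    stop("`lambda` must be positive.", call. = FALSE)
  }
  tibble::tibble(
    r = r,
    lambda = lambda,
    p = lambda / (r + lambda),
    dispersion_index = 1 + lambda / r,
    zero_mass = exp(-r * log1p(lambda / r))
  )
}

# log of the zero mass of a sum of k independent NB(r, mean lambda) counts:
# log P(sum = 0) = -r k log(1 + lambda / r), computed via log1p so that the
# r -> Inf (Poisson) and large-N limits stay accurate.
nb_log_zero <- function(lambda, r, k) {
  -r * k * log1p(lambda / r)
}

#' Conditional non-detection probability under Negative Binomial abundance
#'
#' Analogue of [nondetect_prob()] for overdispersed counts: per-quadrat
#' abundances are independent NB(size `r`, mean `lambda`), so with perfect
#' detection
#'
#' \deqn{p = \frac{(1+\lambda/r)^{-rn} - (1+\lambda/r)^{-rN}}
#'            {1 - (1+\lambda/r)^{-rN}}.}
#'
#' With `delta > 0`, per-individual thinning turns NB(`r`, mean `lambda`)
#' detected counts into NB(`r`, mean `lambda * (1 - delta)`). Two variants of
#' the extension are available (see Details of [n_negbin()]): `"printed"`
#' uses the thinned mean throughout, including inside the terms describing
#' presence in the whole area; `"consistent"` keeps the un-thinned `lambda`
#' in those terms, since detection error cannot change whether the species
#' is present.
#'
#' @inheritParams nondetect_prob
#' @param r Negative Binomial size parameter (positive).
#' @param delta_variant How `delta` enters the finite-area expression;
#'   ignored when `delta = 0` or `area_size = Inf`, where the variants
#'   coincide.
#' @return A single probability in `[0, 1)`.
#' @examples
#' nb_nondetect_prob(0.01, 1, 300, 233)  # above 0.05: NB needs more samples
#' nb_nondetect_prob(0.01, 1e8, 300, 233)  # ~ Poisson value
#' @export
nb_nondetect_prob <- function(lambda, r, area_size, n, delta = 0,
                              delta_variant = c("printed", "consistent")) {
  check_lambda(lambda)
  check_r(r)
  check_area_size(area_size)
  check_delta(delta)
  check_n_samples(n, area_size)
  delta_variant <- match.arg(delta_variant)
  lam_eff <- lambda * (1 - delta)
  top <- exp(nb_log_zero(lam_eff, r, n))
  if (is.infinite(area_size)) {
    return(top)
  }
  lam_area <- if (delta_variant == "printed") lam_eff else lambda
  e_N <- exp(nb_log_zero(lam_area, r, area_size))
  max(0, (top - e_N) / (1 - e_N))
}

#' Minimum number of quadrats under the Negative Binomial abundance model
#'
#' Smallest `n` such that the conditional non-detection probability under
#' NB(size `r`, mean `lambda`) per-quadrat abundance does not exceed `beta`.
#' For a finite area of `N` quadrats and perfect detection,
#'
#' \deqn{n = \left\lceil -\frac{1}{r}\,
#'   \frac{\log\left(\beta + (1-\beta)(1+\lambda/r)^{-rN}\right)}
#'        {\log(1+\lambda/r)} \right\rceil,}
#'
#' and \eqn{n = \lceil -\log(\beta) / (r \log(1+\lambda/r)) \rceil} as
#' \eqn{N \to \infty}. As \eqn{r \to \infty} every formula converges to its
#' Poisson counterpart in [n_poisson()]; at equal mean, finite `r` (more
#' overdispersion, more zero mass) never requires fewer samples.
#'
#' @section Detectability variants:
#' With `delta > 0` and finite `N`, the closed form as printed substitutes
#' the thinned mean `lambda * (1 - delta)` everywhere, including in the
#' `(1 + . / r)^{-rN}` term that stems from the probability that the species
#' is present at all. Thinning affects what is *detected*, not what is
#' *present*, so the package also offers a derivation-consistent variant
#' that keeps the un-thinned `lambda` in the presence terms — exactly as the
#' Poisson formula keeps `exp(-lambda * N)` — and therefore recovers the
#' Poisson answer as `r` grows even when `delta > 0`. The default is the
#' printed form; both reduce to the same expression when `delta = 0`.
#'
#' @inheritParams n_poisson
#' @inheritParams nb_nondetect_prob
#' @return A single positive integer (uncapped when `delta > 0` pushes it
#'   above a finite `N`; see [n_poisson()]).
#' @examples
#' n_negbin(0.05, 0.01, r = 1)          # 302 (infinite area)
#' n_negbin(0.05, 0.01, r = 1, area_size = 300)
#' n_poisson(0.05, 0.01, 300)           # 233: overdispersion costs samples
#' @export
n_negbin <- function(beta, lambda, r, area_size = Inf, delta = 0,
                     delta_variant = c("printed", "consistent")) {
  check_beta(beta)
  check_lambda(lambda)
  check_r(r)
  check_area_size(area_size)
  check_delta(delta)
  delta_variant <- match.arg(delta_variant)
  lam_eff <- lambda * (1 - delta)
  denom <- r * log1p(lam_eff / r)
  if (is.infinite(area_size)) {
    x <- -log(beta) / denom
    ok <- function(m) exp(nb_log_zero(lam_eff, r, m)) <= beta
    return(verified_ceiling(x, ok))
  }
  lam_area <- if (delta_variant == "printed") lam_eff else lambda
  x <- -log(beta + (1 - beta) * exp(nb_log_zero(lam_area, r, area_size))) /
    denom
  ok <- NULL
  if (ceiling(x) <= area_size) {
    ok <- function(m) {
      nb_nondetect_prob(lambda, r, area_size, m, delta, delta_variant) <= beta
    }
  }
  verified_ceiling(x, ok)
}
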