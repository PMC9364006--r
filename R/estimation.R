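#' Estimate the Poisson mean from presence/absence detections
#'
#' Inverts the per-quadrat detection probability. Under Poisson(`lambda`)
#' abundance with per-individual false-negative rate `delta`, a quadrat
#' yields at least one detection with probability
#' `1 - exp(-lambda * (1 - delta))`; with `w` of `n_quadrats` surveyed
#' quadrats showing a detection, the estimator is
#'
#' \deqn{\hat\lambda = \frac{-\log(1 - w/n_0)}{1 - \delta}.}
#'
#' `delta` is treated as known (supplied by the user, e.g. from assay
#' validation); it is not estimated here.
#'
#' @param n_quadrats Number of quadrats surveyed (`n0`), a positive integer.
#' @param detected Number of those quadrats with at least one detection
#'   (`w`), in `[0, n_quadrats]`. `detected == n_quadrats` is an error (the
#'   estimate is unbounded); `detected == 0` returns 0 with a warning, since
#'   every design formula assumes `lambda > 0`.
#' @param delta Known per-individual false-negative probability in `[0, 1)`.
#' @return An object of class `poisson_rate_fit`: a list with `lambda_hat`,
#'   `n_quadrats`, `detected`, `detection_rate`, `delta`. Has [tidy()] and
#'   [glance()] methods and feeds [recommend_n()] via its `estimate`
#'   argument.
#' @examples
#' fit <- estimate_poisson_lambda(200, 37, delta = 0.1)
#' tidy(fit)
#' @export
estimate_poisson_lambda <- function(n_quadrats, detected, delta = 0) {
  if (!is.numeric(n_quadrats) || length(n_quadrats) != 1L ||
      n_quadrats < 1 || n_quadrats != floor(n_quadrats)) {
    stop("`n_quadrats` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(detected) || length(detected) != 1L || detected < 0 ||
      detected > n_quadrats || detected != floor(detected)) {
    stop("`detected` must be an integer in [0, n_quadrats].", call. = FALSE)
  }
  check_delta(delta)
  if (detected == n_quadrats) {
    stop("all ", n_quadrats, " quadrats had detections: the estimate is ",
         "unbounded; increase the number of surveyed quadrats.",
         call. = FALSE)
  }
  if (detected == 0) {
    warning("no detections in any quadrat: lambda_hat = 0, but every design ",
            "formula assumes lambda > 0.", call. = FALSE)
  }
  alpha_hat <- detected / n_quadrats
  structure(
    list(
      lambda_hat = -log(1 - alpha_hat) / (1 - delta),
      n_quadrats = as.integer(n_quadrats),
      detected = as.integer(detected),
      detection_rate = alpha_hat,
      delta = delta
    ),
    class = "poisson_rate_fit"
  )
}

#' Estimate Negative Binomial parameters from per-quadrat counts
#'
#' Method-of-moments estimators from the detected counts
#' \eqn{x_1, \dots, x_{n_0}} (individuals detected per quadrat):
#' \eqn{\hat\lambda = \bar x / (1 - \delta)} and
#' \eqn{\hat r = \bar x^2 / (s^2 - \bar x)}, with \eqn{s^2} the *uncorrected*
#' sample variance (divisor \eqn{n_0}, no Bessel correction). Binomial
#' thinning preserves the size `r` and scales the mean by `1 - delta`, which
#' is why only \eqn{\hat\lambda} carries the `delta` correction. The
#' estimators are the natural biased moment estimators; no bias correction
#' is applied.
#'
#' @param counts Per-quadrat detected counts: a non-negative integer vector,
#'   or a data frame with a `count` column (as produced by
#'   [generate_counts()] or [read_counts()]). At least two quadrats are
#'   needed for the variance.
#' @param delta Known per-individual false-negative probability in `[0, 1)`.
#' @return An object of class `negbin_moment_fit`: a list with `lambda_hat`,
#'   `r_hat`, `dispersion_index` (of the detected counts), `mean`, `var`
#'   (uncorrected), `n_quadrats`, `delta`. Has [tidy()] and [glance()]
#'   methods and feeds [recommend_n()].
#' @examples
#' x <- generate_counts("negbin", lambda = 1, r = 2, n_quadrats = 500, seed = 1)
#' tidy(estimate_negbin(x))
#' @export
estimate_negbin <- function(counts, delta = 0) {
  x <- counts_vector(counts)
  check_delta(delta)
  if (length(x) < 2) {
    stop("at least two quadrat counts are needed to estimate a variance.",
         call. = FALSE)
  }
  xbar <- mean(x)
  s2 <- mean(x^2) - xbar^2  # uncorrected (divisor n0)
  if (xbar == 0) {
    stop("no individuals detected in any quadrat; cannot estimate abundance.",
         call. = FALSE)
  }
  if (s2 <= xbar) {
    stop("counts show no overdispersion (variance <= mean); the moment ",
         "estimate of `r` is undefined. Use the Poisson model instead.",
         call. = FALSE)
  }
  structure(
    list(
      lambda_hat = xbar / (1 - delta),
      r_hat = xbar^2 / (s2 - xbar),
      dispersion_index = s2 / xbar,
      mean = xbar,
      var = s2,
      n_quadrats = length(x),
      delta = delta
    ),
    class = "negbin_moment_fit"
  )
}

counts_vector <- function(counts) {
  x <- if (is.data.frame(counts)) {
    if (!"count" %in% names(counts)) {
      stop("a counts data frame must have a `count` column.", call. = FALSE)
    }
    counts$count
  } else {
    counts
  }
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop("`counts` must be non-negative integers.", call. = FALSE)
  }
  as.numeric(x)
}

#' @export
print.poisson_rate_fit <- function(x, ...) {
  cat("Poisson abundance estimate (presence/absence inversion)\n")
  cat(sprintf("  lambda_hat = %.6g  (detections in %d of %d quadrats, delta = %g)\n",
              x$lambda_hat, x$detected, x$n_quadrats, x$delta))
  invisible(x)
}

#' @export
print.negbin_moment_fit <- function(x, ...) {
  cat("Negative Binomial moment estimate\n")
  cat(sprintf("  lambda_hat = %.6g, r_hat = %.6g  (n0 = %d, delta = %g)\n",
              x$lambda_hat, x$r_hat, x$n_quadrats, x$delta))
  cat(sprintf("  detected-count dispersion index = %.4f\n", x$dispersion_index))
  invisible(x)
}
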