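# broom-style accessors for the package's fitted/simulated objects.

#' @exportS3Method generics::tidy
tidy.poisson_rate_fit <- function(x, ...) {
  tibble::tibble(term = "lambda", estimate = x$lambda_hat)
}

#' @exportS3Method generics::glance
glance.poisson_rate_fit <- function(x, ...) {
  tibble::tibble(
    lambda_hat = x$lambda_hat,
    n_quadrats = x$n_quadrats,
    detected = x$detected,
    detection_rate = x$detection_rate,
    delta = x$delta
  )
}

#' @exportS3Method generics::tidy
tidy.negbin_moment_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "r"),
    estimate = c(x$lambda_hat, x$r_hat)
  )
}

#' @exportS3Method generics::glance
glance.negbin_moment_fit <- function(x, ...) {
  tibble::tibble(
    lambda_hat = x$lambda_hat,
    r_hat = x$r_hat,
    mean = x$mean,
    var = x$var,
    dispersion_index = x$dispersion_index,
    n_quadrats = x$n_quadrats,
    delta = x$delta
  )
}

#' @exportS3Method generics::tidy
tidy.mc_result <- function(x, ...) {
  tibble::tibble(
    term = "nondetect_prob",
    estimate = x$p_hat,
    std.error = x$stderr,
    closed_form = x$closed_form
  )
}

#' @exportS3Method generics::glance
glance.mc_result <- function(x, ...) {
  tibble::tibble(
    p_hat = x$p_hat,
    stderr = x$stderr,
    closed_form = x$closed_form,
    failures = x$failures,
    accepted = x$accepted,
    iterations = x$iterations,
    model = x$model,
    mode = x$mode,
    lambda = x$lambda,
    area_size = x$area_size,
    n = x$n,
    delta = x$delta
  )
}
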