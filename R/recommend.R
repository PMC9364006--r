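#' Build a one-row survey design specification
#'
#' Convenience constructor for the tibble consumed by [recommend_n()]: one
#' row per design question. `area_size` accepts `Inf` (or the string
#' `"inf"`/`"infinite"`) for an effectively unbounded area.
#'
#' @inheritParams n_poisson
#' @param model Abundance model, `"poisson"` or `"negbin"`.
#' @param r Negative Binomial size; required when `model = "negbin"`.
#' @return A one-row tibble with columns `beta`, `lambda`, `area_size`,
#'   `delta`, `model`, `r`.
#' @examples
#' design_spec(0.05, 0.001, area_size = 3000) |> recommend_n()
#' @export
design_spec <- function(beta, lambda, area_size = Inf, delta = 0,
                        model = c("poisson", "negbin"), r = NA_real_) {
  model <- match.arg(model)
  if (is.character(area_size)) {
    if (!tolower(area_size) %in% c("inf", "infinite")) {
      stop("`area_size` must be a positive integer, Inf, or \"infinite\".",
           call. = FALSE)
    }
    area_size <- Inf
  }
  tibble::tibble(
    beta = beta, lambda = lambda, area_size = as.numeric(area_size),
    delta = delta, model = model, r = as.numeric(r)
  )
}

# (model, finite N?, delta > 0?) -> identifier of the closed form used.
formula_id <- function(model, area_size, delta) {
  finite <- is.finite(area_size)
  if (model == "poisson") {
    if (delta > 0) {
      if (finite) "4.1" else "4.4"
    } else {
      if (finite) "2.1" else "1.1"
    }
  } else {
    if (delta > 0) {
      if (finite) "5.4" else "5.5"
    } else {
      if (finite) "5.2" else "5.3"
    }
  }
}

recommend_one <- function(beta, lambda, area_size, delta, model, r,
                          nb_delta_variant) {
  if (model == "negbin") {
    check_r(r)
    n <- n_negbin(beta, lambda, r, area_size, delta, nb_delta_variant)
    prob <- function(m) {
      nb_nondetect_prob(lambda, r, area_size, m, delta, nb_delta_variant)
    }
  } else {
    n <- n_poisson(beta, lambda, area_size, delta)
    prob <- function(m) nondetect_prob(lambda, area_size, m, delta)
  }
  feasible <- is.infinite(area_size) || n <= area_size
  achieved <- if (feasible) prob(n) else prob(area_size)
  tibble::tibble(
    n = as.integer(n),
    formula_id = formula_id(model, area_size, delta),
    feasible = feasible,
    achieved_prob = achieved
  )
}

#' Recommend minimum sample sizes for a table of survey designs
#'
#' Data-frame-first front end to [n_poisson()] and [n_negbin()]: takes one
#' design question per row, dispatches each to the closed form matching its
#' (model, finite-area, detectability) cell, and returns the input with the
#' recommendation appended. Columns `beta` and `lambda` are required;
#' `area_size` (default `Inf`), `delta` (default 0), `model` (default
#' `"poisson"`), and `r` (required for `"negbin"` rows) are optional. The
#' abundance parameters can instead be supplied through `estimate`, the
#' fitted object returned by [estimate_poisson_lambda()] or
#' [estimate_negbin()] — but not both ways at once.
#'
#' @param design A data frame of design questions, e.g. from [design_spec()]
#'   or `tidyr::crossing()`.
#' @param estimate Optional fitted estimate object supplying `lambda` (and
#'   `r`, `delta`, `model` for a Negative Binomial fit).
#' @param nb_delta_variant Variant of the Negative Binomial detectability
#'   formula; see [n_negbin()].
#' @return The input tibble with columns `n` (recommended quadrats),
#'   `formula_id` (closed form used), `feasible` (`n <= area_size`; a
#'   finite-area design with `delta > 0` can be infeasible), and
#'   `achieved_prob` (closed-form non-detection probability at `n`, or at
#'   `area_size` when infeasible).
#' @examples
#' library(dplyr)
#' tidyr::crossing(beta = 0.05, lambda = 0.001,
#'                 area_size = c(3000, 5000, Inf)) |>
#'   recommend_n()
#' @export
recommend_n <- function(design, estimate = NULL,
                        nb_delta_variant = c("printed", "consistent")) {
  nb_delta_variant <- match.arg(nb_delta_variant)
  design <- tibble::as_tibble(design)
  if (!is.null(estimate)) {
    if ("lambda" %in% names(design)) {
      stop("`lambda` supplied both in `design` and through `estimate`; ",
           "use one source.", call. = FALSE)
    }
    design$lambda <- lambda_of(estimate)
    if (inherits(estimate, "negbin_moment_fit")) {
      design$model <- "negbin"
      design$r <- estimate$r_hat
    }
  }
  for (col in c("beta", "lambda")) {
    if (!col %in% names(design)) {
      stop("`design` must have a `", col, "` column.", call. = FALSE)
    }
  }
  if (!"area_size" %in% names(design)) design$area_size <- Inf
  if (!"delta" %in% names(design)) design$delta <- 0
  if (!"model" %in% names(design)) design$model <- "poisson"
  if (!"r" %in% names(design)) design$r <- NA_real_
  res <- purrr::pmap(
    design[c("beta", "lambda", "area_size", "delta", "model", "r")],
    recommend_one,
    nb_delta_variant = nb_delta_variant
  )
  dplyr::bind_cols(design, dplyr::bind_rows(res))
}

lambda_of <- function(estimate) {
  if (!is.list(estimate) || is.null(estimate$lambda_hat)) {
    stop("`estimate` must be a fit from estimate_poisson_lambda() or ",
         "estimate_negbin().", call. = FALSE)
  }
  estimate$lambda_hat
}
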