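#' Plot the required sample size against the area size
#'
#' Shows how the finite-area minimum sample size climbs toward the
#' infinite-area asymptote as the number of quadrats `N` in the area grows —
#' the gap is the saving from using the finite-area formula when `N` is
#' known.
#'
#' @inheritParams n_negbin
#' @param area_sizes Numeric vector of finite area sizes to evaluate.
#' @param model `"poisson"` or `"negbin"`.
#' @return A ggplot object.
#' @examples
#' plot_design_curve(0.05, 0.001, area_sizes = seq(3000, 11000, 500))
#' @export
plot_design_curve <- function(beta, lambda, area_sizes, delta = 0,
                              model = c("poisson", "negbin"), r = NULL,
                              delta_variant = c("printed", "consistent")) {
  model <- match.arg(model)
  delta_variant <- match.arg(delta_variant)
  n_of <- function(N) {
    if (model == "poisson") {
      n_poisson(beta, lambda, N, delta)
    } else {
      n_negbin(beta, lambda, r, N, delta, delta_variant)
    }
  }
  dat <- tibble::tibble(
    area_size = sort(unique(area_sizes)),
    n = purrr::map_int(area_size, n_of)
  )
  asymptote <- n_of(Inf)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$area_size, y = .data$n)) +
    ggplot2::geom_hline(yintercept = asymptote, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("text", x = min(dat$area_size), y = asymptote,
                      label = sprintf("infinite-area n = %d", asymptote),
                      hjust = 0, vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = "area size N (quadrats)",
      y = "minimum samples n",
      title = sprintf("Minimum quadrats for non-detection probability <= %g",
                      beta),
      subtitle = sprintf("%s model, lambda = %g, delta = %g", model, lambda,
                         delta)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_nondetect Plot the Monte Carlo estimate with a
#'   4-standard-error interval against the closed-form probability.
#' @param object An `mc_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mc_result <- function(object, ...) {
  dat <- tibble::tibble(
    estimate = object$p_hat,
    lo = max(0, object$p_hat - 4 * object$stderr),
    hi = object$p_hat + 4 * object$stderr
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = "Monte Carlo", y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = object$closed_form, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = NULL, y = "conditional non-detection probability",
      title = sprintf("p_hat = %.6f vs closed form %.6f",
                      object$p_hat, object$closed_form),
      subtitle = sprintf("%s, N = %g, n = %d, delta = %g, K = %g",
                         object$model, object$area_size, object$n,
                         object$delta, object$iterations)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
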