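#' Monte Carlo estimate of the conditional non-detection probability
#'
#' Simulates the survey: per replicate, species counts are drawn for the
#' `n` sampled and `area_size - n` unsampled quadrats, replicates with no
#' individual anywhere are rejected (conditioning on presence, `Y > 0`),
#' each individual in the sampled quadrats is missed independently with
#' probability `delta`, and the replicate counts as a failure when nothing
#' is detected in the `n` samples. The estimate `failures / accepted`
#' converges to the closed forms in [nondetect_prob()] /
#' [nb_nondetect_prob()] (derivation-consistent variant) by the law of
#' large numbers, which is how the recommended designs are validated.
#'
#' Two equivalent sampling modes are provided. `"aggregated"` (default)
#' draws the totals directly — Poisson(`lambda * n`) and
#' Poisson(`lambda * (N - n)`), or NB with sizes `r * n` and `r * (N - n)` —
#' using the additivity of both families and the fact that per-individual
#' thinning commutes with summation (the detected total is
#' Binomial(total, `1 - delta`)). `"per_quadrat"` draws every quadrat count
#' and thins quadrat by quadrat; it is the literal field process and is
#' only practical for small `area_size`, so it mainly serves to certify the
#' aggregated shortcut.
#'
#' @inheritParams nondetect_prob
#' @param model `"poisson"` or `"negbin"` per-quadrat abundance.
#' @param r Negative Binomial size (required for `model = "negbin"`).
#' @param iterations Number of Monte Carlo replicates `K` (before
#'   rejection of absent-species replicates).
#' @param seed Optional integer seed; identical `seed` + settings give an
#'   identical result.
#' @param mode `"aggregated"` or `"per_quadrat"`.
#' @return An object of class `mc_result`: a list with `p_hat`
#'   (= `failures / accepted`), `accepted`, `failures`, `stderr`
#'   (binomial, `sqrt(p(1-p)/accepted)`), `closed_form` (the matching
#'   analytic probability), plus the settings. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @examples
#' simulate_nondetect(0.01, 300, 233, iterations = 1e5, seed = 1)
#' @export
simulate_nondetect <- function(lambda, area_size, n, delta = 0,
                               model = c("poisson", "negbin"), r = NULL,
                               iterations = 1e6, seed = NULL,
                               mode = c("aggregated", "per_quadrat")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  check_lambda(lambda)
  check_area_size(area_size)
  if (is.infinite(area_size)) {
    stop("Monte Carlo validation needs a finite `area_size`.", call. = FALSE)
  }
  check_delta(delta)
  check_n_samples(n, area_size)
  if (model == "negbin") check_r(r)
  if (!is.numeric(iterations) || iterations < 1) {
    stop("`iterations` must be a positive integer.", call. = FALSE)
  }
  iterations <- as.numeric(iterations)
  if (mode == "per_quadrat" && area_size * min(iterations, 1e6) > 5e8) {
    stop("per_quadrat mode draws area_size x iterations counts; ",
         "use aggregated mode for areas this large.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  chunk_size <- 1e6
  accepted <- 0
  failures <- 0
  remaining <- iterations
  while (remaining > 0) {
    k <- as.integer(min(chunk_size, remaining))
    remaining <- remaining - k
    if (mode == "aggregated") {
      if (model == "poisson") {
        s_n <- rpois(k, lambda * n)
        s_rest <- if (n < area_size) rpois(k, lambda * (area_size - n)) else 0L
      } else {
        s_n <- rnbinom(k, size = r * n, mu = lambda * n)
        s_rest <- if (n < area_size) {
          rnbinom(k, size = r * (area_size - n), mu = lambda * (area_size - n))
        } else 0L
      }
      detected <- if (delta > 0) rbinom(k, s_n, 1 - delta) else s_n
    } else {
      counts <- if (model == "poisson") {
        rpois(area_size * k, lambda)
      } else {
        rnbinom(area_size * k, size = r, mu = lambda)
      }
      m <- matrix(counts, nrow = area_size)
      sampled <- m[seq_len(n), , drop = FALSE]
      s_n <- colSums(sampled)
      s_rest <- if (n < area_size) colSums(m[-seq_len(n), , drop = FALSE]) else 0L
      if (delta > 0) {
        sampled[] <- rbinom(length(sampled), as.vector(sampled), 1 - delta)
      }
      detected <- colSums(sampled)
    }
    present <- (s_n + s_rest) > 0
    accepted <- accepted + sum(present)
    failures <- failures + sum(present & detected == 0)
  }

  if (accepted == 0) {
    stop("no replicate had the species present (lambda * area_size too ",
         "small for ", iterations, " iterations); increase `iterations`.",
         call. = FALSE)
  }
  p_hat <- failures / accepted
  closed <- if (model == "poisson") {
    nondetect_prob(lambda, area_size, n, delta)
  } else {
    nb_nondetect_prob(lambda, r, area_size, n, delta, "consistent")
  }
  structure(
    list(
      p_hat = p_hat,
      accepted = accepted,
      failures = failures,
      stderr = sqrt(p_hat * (1 - p_hat) / accepted),
      closed_form = closed,
      lambda = lambda, area_size = area_size, n = n, delta = delta,
      model = model, r = r, iterations = iterations, mode = mode
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo non-detection probability (%s, %s mode)\n",
              x$model, x$mode))
  cat(sprintf("  p_hat = %.8f  (stderr %.2e, %.0f failures / %.0f accepted of %g)\n",
              x$p_hat, x$stderr, x$failures, x$accepted, x$iterations))
  cat(sprintf("  closed form  = %.8f\n", x$closed_form))
  invisible(x)
}

#' Generate synthetic per-quadrat detected counts
#'
#' Fixture generator matching the package's distributional assumptions:
#' true per-quadrat counts are drawn from Poisson(`lambda`) or
#' NB(size `r`, mean `lambda`), then each individual is retained
#' (detected) independently with probability `1 - delta` (binomial
#' thinning). Thinning maps Poisson(`lambda`) detected counts to
#' Poisson(`lambda * (1 - delta)`) and preserves the NB size `r` while
#' scaling the mean — the properties the estimators in
#' [estimate_poisson_lambda()] and [estimate_negbin()] rely on.
#'
#' @inheritParams simulate_nondetect
#' @param n_quadrats Number of quadrats to simulate (`n0`).
#' @return A tibble with one integer column `count` (detected individuals
#'   per quadrat).
#' @examples
#' generate_counts("poisson", lambda = 0.5, delta = 0.2,
#'                 n_quadrats = 1000, seed = 1)
#' @export
generate_counts <- function(model = c("poisson", "negbin"), lambda,
                            r = NULL, delta = 0, n_quadrats, seed = NULL) {
  model <- match.arg(model)
  check_lambda(lambda)
  check_delta(delta)
  if (model == "negbin") check_r(r)
  if (!is.numeric(n_quadrats) || length(n_quadrats) != 1L || n_quadrats < 1 ||
      n_quadrats != floor(n_quadrats)) {
    stop("`n_quadrats` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  true_counts <- if (model == "poisson") {
    rpois(n_quadrats, lambda)
  } else {
    rnbinom(n_quadrats, size = r, mu = lambda)
  }
  detected <- if (delta > 0) {
    rbinom(n_quadrats, true_counts, 1 - delta)
  } else {
    true_counts
  }
  tibble::tibble(count = as.integer(detected))
}
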