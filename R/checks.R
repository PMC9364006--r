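# Internal argument validators. All design formulas share the same domain:
# beta in (0,1), lambda > 0, area_size a positive integer or Inf,
# delta in [0,1) (delta = 1 gives an infinite sample size and is rejected),
# r > 0 for the Negative Binomial.

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta >= 1) {
    stop("`beta` must be a single probability strictly between 0 and 1.",
         call. = FALSE)
  }
  invisible(beta)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single positive number (mean individuals per quadrat).",
         call. = FALSE)
  }
  invisible(lambda)
}

check_area_size <- function(area_size) {
  if (!is.numeric(area_size) || length(area_size) != 1L || is.na(area_size)) {
    stop("`area_size` must be a positive integer or Inf.", call. = FALSE)
  }
  if (!is.infinite(area_size) &&
      (area_size < 1 || area_size != floor(area_size))) {
    stop("`area_size` must be a positive integer or Inf.", call. = FALSE)
  }
  invisible(area_size)
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta >= 1) {
    stop("`delta` must be in [0, 1); delta = 1 means individuals are never ",
         "detected and no finite sample size exists.", call. = FALSE)
  }
  invisible(delta)
}

check_r <- function(r) {
  if (is.null(r) || !is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a single positive number (Negative Binomial size).",
         call. = FALSE)
  }
  invisible(r)
}

check_n_samples <- function(n, area_size) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != floor(n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  if (!is.infinite(area_size) && n > area_size) {
    stop("`n` cannot exceed `area_size`: the area only holds ", area_size,
         " quadrats.", call. = FALSE)
  }
  invisible(n)
}

# Ceiling with a verification pass: the real-valued bound `x` is computed in
# double precision, so when x sits within floating-point noise of an integer
# ceiling() can land one off. `ok(m)` evaluates the defining inequality
# (closed-form non-detection probability at m samples <= beta); the candidate
# is nudged by +-1 until it is the smallest integer passing it. `ok` may be
# NULL when the inequality cannot be evaluated (infeasible n > N).
verified_ceiling <- function(x, ok = NULL) {
  k <- max(1L, as.integer(ceiling(x - 1e-12)))
  if (!is.null(ok)) {
    if (k > 1L && ok(k - 1L)) k <- k - 1L
    if (!ok(k)) k <- k + 1L
  }
  k
}
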