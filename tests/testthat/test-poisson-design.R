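test_that("infinite-area sample size matches the closed form and is minimal", {
  expect_identical(n_poisson(0.05, 0.001), 2996L)
  expect_identical(n_poisson(0.05, 0.01), 300L)
  # when -log(beta)/lambda is exactly an integer the ceiling must not slip
  for (lam in c(0.3, 1, 2.5)) {
    expect_identical(n_poisson(exp(-lam), lam), 1L)
    expect_identical(n_poisson(exp(-7 * lam), lam), 7L)
  }
})

test_that("finite-area sample size reproduces the reference ladder exactly", {
  tab <- table1_expected()
  got <- purrr::pmap_int(tab[c("beta", "lambda", "area_size")],
                         \(beta, lambda, area_size) n_poisson(beta, lambda, area_size))
  expect_identical(got, tab$n_finite)
  expect_identical(
    purrr::map2_int(tab$beta, tab$lambda, n_poisson),
    tab$n_infinite
  )
})

test_that("detectability-adjusted sample sizes reproduce the reference values", {
  tab <- table3_expected()
  got_fin <- purrr::pmap_int(tab[c("area_size", "delta")],
                             \(area_size, delta) n_poisson(0.05, 0.001, area_size, delta))
  got_inf <- purrr::map_int(tab$delta, \(d) n_poisson(0.05, 0.001, Inf, d))
  expect_identical(got_fin, tab$n_finite)
  expect_identical(got_inf, tab$n_infinite)
})

test_that("delta = 0 reduces the adjusted formulas to the error-free ones", {
  grid <- design_grid(deltas = 0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(n_poisson(g$beta, g$lambda, g$area_size, 0),
                     n_poisson(g$beta, g$lambda, g$area_size))
    expect_identical(n_poisson(g$beta, g$lambda, Inf, 0),
                     n_poisson(g$beta, g$lambda))
  }
})

test_that("returned n is the scan-minimal integer meeting the bound", {
  grid <- design_grid()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- n_poisson(g$beta, g$lambda, g$area_size, g$delta)
    scan <- scan_min_n(g$beta, g$area_size, function(m) {
      (exp(-g$lambda * m * (1 - g$delta)) - exp(-g$lambda * g$area_size)) /
        (1 - exp(-g$lambda * g$area_size))
    })
    if (n <= g$area_size) {
      expect_identical(n, as.integer(scan))
    } else {
      # infeasible: no m within the area meets the bound, and the uncapped
      # n still satisfies the unconditional inequality
      expect_true(is.na(scan))
      expect_gt(g$delta, 0)
      expect_lte(exp(-g$lambda * n * (1 - g$delta)),
                 g$beta + (1 - g$beta) * exp(-g$lambda * g$area_size))
    }
  }
})

test_that("n is within the area for delta = 0 and monotone in each parameter", {
  grid <- design_grid(deltas = 0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- n_poisson(g$beta, g$lambda, g$area_size)
    expect_gte(n, 1L)
    expect_lte(n, g$area_size)
  }
  # nonincreasing in beta and lambda; nondecreasing in area size (toward the
  # infinite-area ceiling) and in the false-negative rate
  expect_true(all(diff(sapply(c(0.01, 0.05, 0.2),
                              \(b) n_poisson(b, 0.001, 3000))) <= 0))
  expect_true(all(diff(sapply(c(0.001, 0.01, 0.1, 1),
                              \(l) n_poisson(0.05, l, 3000))) <= 0))
  n_by_N <- sapply(c(10, 300, 3000, 30000), \(N) n_poisson(0.05, 0.001, N))
  expect_true(all(diff(n_by_N) >= 0))
  expect_true(all(n_by_N <= n_poisson(0.05, 0.001)))
  expect_true(all(diff(sapply(c(0, 0.1, 0.5, 0.9),
                              \(d) n_poisson(0.05, 0.001, 3000, d))) >= 0))
})

test_that("finite-area answer converges to the infinite-area one as N grows", {
  for (b in c(0.2, 0.05)) {
    for (l in c(0.01, 0.1)) {
      ninf <- n_poisson(b, l)
      ns <- sapply(2^(0:14) * 10, \(N) n_poisson(b, l, N))
      expect_identical(ns[length(ns)], ninf)
      expect_true(all(ns <= ninf))
    }
  }
})

test_that("overestimation is bounded and attains bound - 1 for large N", {
  expect_identical(overestimation_bound(0.05, 0.001, 3000), 666L)
  expect_identical(n_poisson(0.05, 0.001) - n_poisson(0.05, 0.001, 3000), 666L)
  grid <- design_grid()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    diff <- n_poisson(g$beta, g$lambda, Inf, g$delta) -
      n_poisson(g$beta, g$lambda, g$area_size, g$delta)
    expect_gte(diff, 0L)
    expect_lte(diff, overestimation_bound(g$beta, g$lambda, g$area_size,
                                          g$delta))
  }
  # for N large enough the difference stabilizes at exactly bound - 1
  # (below the stabilization point it occasionally touches the bound itself)
  Ns <- seq(3000, 20000, by = 500)
  eq <- sapply(Ns, \(N) {
    d <- n_poisson(0.05, 0.001) - n_poisson(0.05, 0.001, N)
    d == overestimation_bound(0.05, 0.001, N) - 1L
  })
  expect_true(any(eq))
  expect_true(all(eq[Ns >= 10500]))
})

test_that("conditional non-detection probability matches an independent derivation", {
  # whole area sampled with perfect detection: failure is impossible
  expect_identical(nondetect_prob(0.01, 300, 300), 0)
  # recommended n sits just under the bound
  p <- nondetect_prob(0.001, 3000, 2330)
  expect_lte(p, 0.05)
  expect_lt(0.05 - p, 0.001)
  # individual-allocation oracle (binomial placement of Y individuals)
  cases <- tidyr::crossing(lambda = c(0.05, 0.3), area_size = c(8, 40),
                           delta = c(0, 0.25, 0.6))
  for (i in seq_len(nrow(cases))) {
    g <- cases[i, ]
    n <- max(1, g$area_size %/% 3)
    expect_equal(
      nondetect_prob(g$lambda, g$area_size, n, g$delta),
      allocation_oracle(g$lambda, g$area_size, n, g$delta),
      tolerance = 1e-10
    )
  }
  # monotone increasing in the false-negative rate
  ds <- c(0, 0.1, 0.3, 0.5, 0.9)
  ps <- sapply(ds, \(d) nondetect_prob(0.01, 300, 100, d))
  expect_true(all(diff(ps) > 0))
})

test_that("domain violations are rejected", {
  expect_error(n_poisson(0, 0.001), "beta")
  expect_error(n_poisson(1, 0.001), "beta")
  expect_error(n_poisson(0.05, 0), "lambda")
  expect_error(n_poisson(0.05, 0.001, 0), "area_size")
  expect_error(n_poisson(0.05, 0.001, 10.5), "area_size")
  expect_error(n_poisson(0.05, 0.001, 3000, 1), "delta")
  expect_error(n_poisson(0.05, 0.001, 3000, -0.1), "delta")
  expect_error(nondetect_prob(0.01, 300, 301), "exceed")
  expect_error(nondetect_prob(0.01, 300, 0), "positive integer")
})
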