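---
title: "Designing quadrat surveys to detect a species that is present"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing quadrat surveys to detect a species that is present}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadratdesign)
library(dplyr)
```

## The design question

A survey team wants to establish whether a target species is present in an
area — an invasive pest, a threatened plant, an incipient infestation. The
area is divided into `N` non-overlapping unit quadrats; `n` of them are
sampled at random, and the species is declared detected if at least one
individual is found. How large must `n` be so that, *given the species is
actually present in the area*, the probability of seeing nothing in all `n`
quadrats is at most a tolerance `beta`?

`quadratdesign` answers this for two abundance models:

* **Poisson**: per-quadrat counts `X_i ~ Pois(lambda)`, independent, so the
  area total is `Y ~ Pois(lambda * N)`. Appropriate for sparse populations
  with no overdispersion.
* **Negative Binomial** (size `r`, mean `lambda`): variance
  `lambda * (1 + lambda / r) > lambda`, zero mass
  `(1 + lambda/r)^(-r) > exp(-lambda)`. One model that captures both
  overdispersion and zero inflation; the Poisson is its `r -> Inf` limit.

Imperfect detectability enters as a per-individual false-negative rate
`delta`: each individual present in a sampled quadrat is independently
missed with probability `delta` (false positives are assumed impossible).
`delta` is treated as known — supplied from assay validation or expert
knowledge — and is never estimated by the package.

## The conditional non-detection probability

The quantity being bounded is a *conditional* probability. Writing `S_n` for
the count in the `n` sampled quadrats, independence of quadrats splits the
area total into `S_n` and the remainder, giving under the Poisson model

$$
P(\text{nothing detected} \mid Y > 0)
  = \frac{e^{-\lambda n (1-\delta)} - e^{-\lambda N}}{1 - e^{-\lambda N}},
$$

implemented in `nondetect_prob()`. The `delta` term arises because "nothing
detected" is the union of "no individuals in the samples" and "individuals
present but every one missed", and summing the thinned Poisson series
collapses both into the single thinned rate `lambda * (1 - delta)`.
Conditioning matters: treating `P(Y > 0)` as 1 (the classical infinite-area
shortcut) systematically overestimates `n` when `N` is known and moderate.

Inverting the inequality `p <= beta` for integer `n` gives the closed forms
dispatched by `recommend_n()` and summarized by `reproduce_table(4)`:

| model | finite area, `delta = 0` | finite area, `delta > 0` | `N -> Inf` |
|---|---|---|---|
| Poisson | `2.1` | `4.1` | `1.1` / `4.4` |
| Neg. Binomial | `5.2` | `5.4` | `5.3` / `5.5` |

For the Poisson with `delta = 0` the recommended `n` provably satisfies
`1 <= n <= N`. With `delta > 0` no such guarantee exists: if even sampling
all `N` quadrats cannot push the non-detection probability below `beta`, the
formula value exceeds `N`. The package *never caps* this value — capping
would silently void the `beta` guarantee — and instead flags the row
`feasible = FALSE`, reporting the probability achieved at `n = N`.

```{r}
recommend_n(design_spec(0.2, 0.001, area_size = 10, delta = 0.5))
```

## Worked example

With `beta = 0.05` and `lambda = 0.001` the infinite-area answer is 2996
quadrats. If the area is known to hold `N = 3000` quadrats, conditioning on
presence saves 666 of them:

```{r}
tidyr::crossing(beta = 0.05, lambda = 0.001,
                area_size = c(3000, 5000, 10000, Inf)) |>
  recommend_n()
```

`reproduce_table(1)` sweeps this ladder for both worked examples
(`lambda = 0.001` and `lambda = 0.01`); `reproduce_table(3)` repeats the
exercise across false-negative rates, where e.g. `delta = 0.5` at
`N = 6000` pushes the recommendation from 2950 to 5900 quadrats.

## Tunable parameters

* `beta` — tolerated conditional non-detection probability, unitless in
  `(0, 1)`. No default: it is a policy choice (0.05 in the worked examples).
* `lambda` — expected individuals per quadrat (per unit area). Estimated
  from pilot data when unknown (below).
* `area_size` — number of quadrats `N` in the area; `Inf` is a first-class
  value dispatching to the infinite-area formulas rather than being
  emulated by a huge finite `N`, which would underflow `exp(-lambda * N)`.
* `delta` — per-individual false-negative probability, `[0, 1)`. `delta = 1`
  is rejected: the required `n` diverges.
* `r` — Negative Binomial size. Accepted as any positive real (the closed
  forms and the moment estimator are well defined off the integers).

## The two Negative Binomial detectability variants

For the Poisson, thinning affects only the sampled-and-missed term: the
`exp(-lambda * N)` terms describe whether the species is *present*, which
detection error cannot change. The finite-area Negative Binomial formula
with detection error, as conventionally written, substitutes the thinned
mean `lambda * (1 - delta)` throughout — including in the
`(1 + lambda(1-delta)/r)^{-rN}` presence term. The two readings genuinely
differ: the all-thinned form does not converge to the Poisson answer as
`r -> Inf` unless `delta = 0`, and can even recommend fewer samples than
the Poisson model at equal mean.

Rather than guessing intent, both are implemented behind
`delta_variant = c("printed", "consistent")`. The default `"printed"`
evaluates the conventional expression exactly; `"consistent"` keeps the
un-thinned `lambda` in the presence terms, mirrors the Poisson derivation,
and recovers it in the `r -> Inf` limit. They coincide whenever
`delta = 0` or `area_size = Inf`. The Monte Carlo simulator estimates the
physical process (thinning applied to sampled individuals only), so it
matches the `"consistent"` closed form; the test suite's Poisson-limit
checks use that variant for `delta > 0`.

## Estimating the abundance parameters

* Poisson: from `w` detections among `n0` surveyed quadrats,
  `lambda_hat = -log(1 - w/n0) / (1 - delta)` (`estimate_poisson_lambda()`),
  inverting the per-quadrat detection probability
  `1 - exp(-lambda (1 - delta))`. `w = n0` is an error (unbounded
  estimate); `w = 0` returns 0 with a warning since every design formula
  needs `lambda > 0`.
* Negative Binomial: method of moments on the detected counts,
  `lambda_hat = xbar / (1 - delta)`, `r_hat = xbar^2 / (s2 - xbar)` with
  `s2` the *uncorrected* (divisor `n0`) sample variance
  (`estimate_negbin()`). Binomial thinning preserves `r` and scales the
  mean, so only `lambda_hat` carries the `delta` correction. These are the
  natural biased moment estimators; no bias correction or likelihood
  fitting is offered, and `s2 <= xbar` is an error recommending the
  Poisson model rather than a silently infinite `r_hat`.

Both fits feed `recommend_n(design, estimate = fit)` directly.

## Monte Carlo validation

`simulate_nondetect()` replays the survey: draw the species counts, reject
replicates where no individual exists anywhere (conditioning on `Y > 0` by
rejection, the direct analogue of the conditional probability), thin the
sampled individuals, and count replicates with zero detections. Two modes:

* `aggregated` (default): draws the region totals —
  `Pois(lambda n)` / `Pois(lambda (N-n))`, or NB sizes `r n` / `r (N-n)` —
  valid because both families are additive and per-individual thinning
  commutes with summation. This is what makes `K = 10^7` replicates at
  `N = 3000` take seconds rather than the `3 x 10^10` per-quadrat draws the
  literal protocol would need.
* `per_quadrat`: the literal protocol, one draw per quadrat, retained to
  certify the aggregated shortcut at small `N` (the suite compares them at
  `N <= 50` within joint Monte Carlo error).

Uncertainty is the binomial standard error over accepted replicates; the
suite's agreement checks use a 4-standard-error band, a per-comparison
false-alarm rate of about `6e-5`.

## What the synthetic generator does and does not emulate

`generate_counts()` draws independent per-quadrat counts from exactly the
assumed distributions and applies exact binomial thinning. Recovery tests
on its output therefore certify the estimators and the formula plumbing
*under the model*: independence across quadrats, spatial homogeneity of
`lambda`, a constant known `delta`, unbiased (random) quadrat placement.
Real field data violate these in ways the generator deliberately does not
reproduce — spatial clustering beyond what the NB absorbs, habitat-driven
trends in `lambda`, observer-dependent or abundance-dependent `delta`,
biased or opportunistic sampling. Passing tests say nothing about those
failure modes; they say the mathematics is implemented correctly.

## Numerical choices

* All logarithms are natural; ceilings use the smallest-integer-not-less
  convention.
* Every closed-form `n` is re-verified against its defining probability
  inequality at the candidate and candidate − 1, so a real-valued bound
  landing within floating-point noise of an integer cannot shift the
  answer by one.
* Negative Binomial powers `(1 + lambda/r)^{-rk}` are evaluated as
  `exp(-r k log1p(lambda / r))`, which keeps the `r = 1e8` Poisson-limit
  checks exact to the integer and avoids overflow at extreme `r N`.
* The Monte Carlo loop draws in fixed chunks of `1e6` replicates, so a
  seed fully determines the result regardless of `K`.

## Problem sizes used by the checks

The property tests sweep `beta` in {0.2, 0.05, 0.01}, `lambda` in
{0.001, 0.01, 0.1, 1}, `N` in {10, 300, 3000} and `delta` in {0, 0.1, 0.5},
with linear-scan minimality oracles over the full `1..N` range. Monte
Carlo spot checks run at `K = 1e5`–`2e5` replicates, with the headline
validation of the `N = 3000` design at `K = 10^7`; estimator-recovery
checks use `n0 = 1e5` quadrats. These sizes make the whole suite run in
well under a minute while keeping every Monte Carlo band at or below the
per-comparison false-alarm rate quoted above.

## Limitations

* No false positives (`f_p = 0` throughout) and no estimation of `delta`.
* No spatially explicit or biased sampling; quadrats are exchangeable.
* No explicit zero-inflated mixtures (ZIP/ZINB); the Negative Binomial is
  the single overdispersion/zero-inflation model.
* The moment estimators are biased in small samples; no interval estimates
  are provided.
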