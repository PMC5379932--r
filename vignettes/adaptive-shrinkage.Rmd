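---
title: "Adaptive shrinkage: model, fitting, and simulation protocols"
author: "ebshrink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive shrinkage: model, fitting, and simulation protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebshrink)
```

## The model and its assumptions

The data are pairs $(\hat\beta_j, \hat s_j)$, $j = 1,\dots,J$: an estimate of
each effect and its standard error. Two assumptions drive everything:

1. **Unimodality.** The true effects $\beta_j$ are i.i.d. from a distribution
   $g$ with a single mode (default at zero). Scientifically: if "exactly
   zero" is plausible, "very small" must be at least as plausible, and larger
   effects are rarer. The prior is written as a point mass plus a fixed grid
   of scale components,
   $$g(\cdot) = \pi_0\,\delta_0(\cdot) + \sum_{k=1}^K \pi_k f_k(\cdot),$$
   with $f_k$ either zero-mean normals $N(0,\sigma_k^2)$
   (`mixcompdist = "normal"`), symmetric uniforms $U(-\sigma_k,\sigma_k)$
   (`"uniform"`), or half-uniform pairs $U(-\sigma_k,0), U(0,\sigma_k)$
   (`"halfuniform"`). The uniform families can approximate *any* unimodal
   distribution as the grid densifies; the half-uniforms additionally allow
   asymmetry. Only the weights $\pi$ are free — the grid is never estimated,
   which keeps the fitting problem convex.

2. **A likelihood that carries precision.** $\hat\beta_j \mid \beta_j \sim
   N(\beta_j, \hat s_j^2)$ (or $\beta_j + \hat s_j T_\nu$ with `df` set).
   Observations with large $\hat s_j$ have flat likelihoods and are
   automatically down-weighted — they cannot contaminate the information
   carried by precise observations, unlike in p-value based pipelines.

Independence across tests (and of $\hat s$ from $\beta$, unless $\alpha > 0$,
below) is assumed throughout; correlated tests and confounding are out of
scope.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mixcompdist` | `"normal"` | component family (see above) |
| `lambda0` | 10 | Dirichlet-type penalty weight on $\pi_0$; 1 disables |
| `gridmult` | $\sqrt 2$ | geometric spacing of the scale grid |
| `pointmass` | `TRUE` | include $\delta_0$; off asserts no exact nulls |
| `alpha` | 0 | exponent in $\beta_j/\hat s_j^\alpha \sim g$; `"estimate"` for ML grid search |
| `mode` | 0 | prior mode (effect units); `"estimate"` for profile ML |
| `ci_level` | 0.95 | credible level for interval and one-sided bound |
| `tol`, `maxiter` | $10^{-7}$, 5000 | EM stopping rule (relative penalized log-likelihood change) |

**Grid.** Scales run geometrically from $\sigma_{\min} = \min(\hat s)/10$
(well below the measurement resolution) up to the first grid point at or
above $\sigma_{\max} = 2\sqrt{\max(\hat\beta^2 - \hat s^2)}$ (comfortably
beyond the largest plausible effect), floored so degenerate data still
produce a one-scale grid. With `gridmult = sqrt(2)` the finite grid is dense
enough that the weight optimum changes negligibly under further refinement;
both endpoint rules are configurable through `build_grid()`.

**Penalty.** The fitted weights maximize
$\sum_j \log \sum_k \pi_k L_{jk} + (\lambda_0 - 1)\log\pi_0$. With
$\lambda_0 = 10$ this adds nine pseudo-counts to the null component —
negligible for the fit quality but enough to prefer the largest $\pi_0$
consistent with the data, so that lfdr/q-values err conservative. The same
form supports penalties on other components (`fit_pi`'s `lambda`), which we
leave at 1.

**$\alpha$.** With $\alpha = 1$, effects scale with their standard errors and
all inference depends on the data only through $z_j = \hat\beta_j/\hat s_j$;
lfsr becomes monotone in the two-sided p-value, reproducing classical
orderings. `alpha = "estimate"` scores each candidate by the original-scale
marginal likelihood (adding the Jacobian term $-\alpha\sum_j\log\hat s_j$),
with ties broken toward the smaller (less aggressive) value.

## Posterior summaries

Each observation's posterior is an analytic mixture: the point mass, conjugate
normals $N\!\big(\hat\beta_j\sigma_k^2/(\sigma_k^2+\hat s_j^2),\,
\sigma_k^2\hat s_j^2/(\sigma_k^2+\hat s_j^2)\big)$, and noise distributions
truncated to the uniform supports. From it we report:

* `lfdr` $= \Pr(\beta_j = 0 \mid \text{data})$ and `lfsr`
  $= \min\{\Pr(\beta_j \le 0), \Pr(\beta_j \ge 0)\}$. Sign probabilities are
  always taken about zero — the scientific sign — even when the prior mode is
  shifted, so a shifted point mass contributes to a sign probability, not to
  lfdr. Both tails include the atom, hence lfsr $\ge$ lfdr always.
* Posterior mean/SD by standard mixture moments.
* Credible bounds by the generalized inverse
  $q(p) = \inf\{x : F(x) \ge p\}$ of the atom-bearing mixture cdf, solved by
  bisection to $10^{-8}$; a quantile falling inside the atom returns the atom
  location exactly. The reported `CredibleLower`/`CredibleUpper` are the
  two-sided interval; coverage experiments use the one-sided lower bound
  $q(1-\gamma)$, stored as `fit$lower_bound`. We default to the one-sided
  reading of "95% lower credible bound" (switchable by taking the two-sided
  endpoint instead) because that is the bound whose nominal
  $\Pr(\beta_j \ge b_j) = 0.95$ the coverage experiment interrogates.
* `svalue`/`qvalue`: cumulative means of sorted lfsr/lfdr, ties pooled by the
  $\le$-set definition so the result is order-independent.

## Numerical choices

* All component log-likelihoods are cdf differences computed in log space,
  switching to the complementary tail when both arguments lie right of the
  mode; stable for $|z|$ up to 40 (verified by two-route agreement to
  $10^{-10}$).
* Truncated-normal moments use the standard $\phi/\Phi$ ratios; intervals so
  deep in the tail that the normalizer underflows collapse to the nearest
  endpoint (such components carry posterior weight $< 10^{-300}$).
* Truncated-t moments (t likelihood, uniform components only — the
  normal-component/t convolution has no closed form and is rejected) use
  64-point Gauss–Legendre quadrature; sign probabilities use closed-form t
  cdf differences.
* A uniform component narrower than $10^{-12}$ is treated as a point mass at
  its midpoint.
* EM is accelerated by a squared-extrapolation step, guarded to fall back to
  the plain EM update whenever extrapolation would decrease the penalized
  objective, so the objective trace is monotone by construction. The
  objective is concave, so the converged point is the global optimum
  (cross-checked against brute-force simplex scans in the tests).
* Weight initialization is deterministic: uniform with the null component
  boosted to half mass. The whole fit is deterministic given data and
  options.

## What the simulator emulates

`simulate_dataset()` reproduces the benchmark protocol: draw
$\pi_0 \sim U[0,1]$ (or fix it), draw $\beta_j \sim \pi_0\delta_0 +
(1-\pi_0)g_1$, then $\hat\beta_j \sim N(\beta_j, s_j^2)$ with $s_j \equiv 1$
or a half-and-half $\{1, 10\}$ mix. The six named $g_1$ shapes
(`default_scenarios()`) span a near-unidentifiable "spiky" scale mixture, a
"near-normal", a "flat-top" plateau, an asymmetric "skew", a wide
"big-normal", and a "bimodal" shape that deliberately violates unimodality.
The harness takes these as configurable mixture specifications, so variant
parameterizations can be dropped in.

What it does *not* emulate — and what passing tests therefore do not
demonstrate — includes correlation among tests, estimated (noisy) standard
errors with few degrees of freedom, and confounded designs. Real data carry
all three.

### Experiment protocols and problem sizes

Each experiment uses 100 datasets of $J = 1000$ per scenario (the protocol
size), run with fixed seeds; smaller unit tests use reduced replicates. The
coverage experiment pools observations across datasets and reports the
fraction with $\beta_j \ge q(0.05)$, overall and for significant discoveries
(lfsr $\le 0.05$, a threshold we fix by convention) split by sign of the
posterior mean. The contamination experiment uses 5000 good-precision and
5000 poor-precision observations with effects half null, half $N(0,1)$.

### A note on null-proportion calibration

In scenarios with substantial effect mass near zero, $\pi_0$ is not
identifiable from above and the penalized estimator overestimates it in
$\ge 95\%$ of datasets (spiky, near-normal, skew). In the identifiable
big-normal scenario the estimator is nearly unbiased — the nine-pseudo-count
penalty shifts $\hat\pi_0$ by only $\approx +0.01$, within sampling noise —
so roughly 40% of those datasets come out slightly *below* the truth, and
the pooled conservative fraction across the five unimodal scenarios lands
near 0.87 rather than above 0.9. This is a property of the estimator at
$\lambda_0 = 10$, not a fitting defect; raising `lambda0` buys more
conservatism at the cost of over-shrinkage (visible as reduced coverage in
the spiky scenario). The lfsr is the robust summary precisely because it is
insensitive to this $\pi_0$ ambiguity.

## Known limitations

* Uniform-family grids can curtail the extreme tail of $g$, understating the
  magnitude of outlying effects (visible as slight under-coverage for
  significant discoveries in long-tailed scenarios).
* The point-mass penalty over-shrinks when the truth is spiky but non-null;
  coverage of one-sided bounds dips to $\approx 0.90$ there.
* No uncertainty in $\hat g$ is propagated into the posteriors (empirical
  Bayes, not fully Bayes).
* The t likelihood requires uniform-family components.
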