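---
title: "Centering the lagged predictor in multilevel autoregressive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centering the lagged predictor in multilevel autoregressive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inertia)
```

## The model

Intensive longitudinal designs (daily diaries, experience sampling)
yield many occasions `t = 1..T` nested in persons `i = 1..N`. When the
interest is in *inertia* — how strongly a deviation from a person's
equilibrium carries over to the next occasion — the natural model is a
two-level AR(1) process:

$$y_{ti} = \mu_i + a_{ti}, \qquad a_{ti} = \phi_i\, a_{t-1,i} + e_{ti},
\qquad e_{ti} \sim N(0, \sigma^2_e),$$

with person-specific equilibria and inertias modelled at level 2:

$$\mu_i = \mu + u_{0i}, \qquad \phi_i = \phi + u_{1i},$$

where $(u_{0i}, u_{1i})$ are jointly Gaussian with variances
$\sigma^2_{u0}$, $\sigma^2_{u1}$ and covariance $\sigma_{u0,u1}$.
Stationarity requires $|\phi_i| < 1$; empirically inertia tends to lie
between 0 and 0.6.

Standard mixed-model software wants a single level-1 equation, which
forces a choice of parameterization for the lagged predictor
$y_{t-1,i}$:

* **NC (no centering)** — $y_{ti} = c_i + \phi_i\, y_{t-1,i} + e_{ti}$.
  The random intercept is $c_i = \mu_i (1 - \phi_i)$, an extrapolation
  of limited substantive interest; `transform_nc_params()` maps the
  fitted intercept back to the mean scale via
  $\hat\mu = \hat\gamma_{00} / (1 - \hat\gamma_{10})$. Note the two
  parameterizations place the normality assumption on different
  level-2 quantities ($c_i$ vs $\mu_i$), so they are structurally but
  not statistically identical.
* **CMC (cluster-mean centering)** —
  $y_{ti} = \mu_i + \phi_i (y_{t-1,i} - \mu_i) + e_{ti}$. The random
  intercept is the person's mean, and level-2 predictors act on
  interpretable quantities. The catch: $\mu_i$ must be estimated
  before it can be subtracted. The package supports the sample mean
  $\bar y_{\cdot i}$, the empirical-Bayes shrinkage mean
  $\hat\mu_i = \hat\gamma_{00} + \lambda_i(\bar y_{\cdot i} -
  \hat\gamma_{00})$ with
  $\lambda_i = \sigma^2_{u0}/(\sigma^2_{u0} + \sigma^2_e/T_i)$, and —
  for simulated data — the true generating mean.
* **GMC (grand-mean centering)** — subtracting one pooled constant; an
  exact reparameterization of NC (identical slope and likelihood),
  kept for completeness and tested to near machine precision.

## Why centering matters here

For an ordinary level-1 predictor whose within-cluster slope $\beta_W$
differs from its between-cluster slope $\beta_B$, the classical advice
holds: an uncentered mixed model estimates an uninterpretable blend of
the two, and CMC isolates $\beta_W$. The package's standard-model
simulator (`simulate_standard()`) reproduces this: the uncentered slope
moves from $\beta_W$ toward $\beta_B$ as the intercept variance
$\sigma^2_{u0}$ shrinks relative to the noise $\sigma^2_e$.

A lagged outcome is different in two ways. First, the between-cluster
slope of a stationary series on its own lag is essentially 1 by
construction (cluster means of the series and its lag coincide up to
edge terms), so $\beta_W < \beta_B$ always. Second — and this is the
core phenomenon — subtracting an *estimated-from-the-same-series* (or
even the true) cluster mean induces the dynamic-panel (Nickell-type)
bias: the pooled demeaned AR(1) slope estimator is biased downward by

$$E[\hat\phi] - \phi \approx -\frac{1 + \phi}{T - 1},$$

about $-0.07$ at $\phi = 0.3$, $T = 20$. The bias is negative for every
stationary $\phi$, worse for positive $\phi$, shrinks like $1/T$, and is
*independent of N* — which is why adding persons makes CMC's confidence
intervals collapse around the wrong value (coverage near 0.2 at
$N = 100$, $T = 20$) while leaving the bias untouched. The uncentered
fit does not subtract a mean and shows no such bias. With a level-2
predictor of inertia the trade-off reverses: CMC estimates the
cross-level effect $\gamma_{11}$ with less bias than NC. Hence the dual
advice the package's reporting follows: NC for the average inertia, CMC
for the grand mean and level-2 effects.

`within_bias_approx()` implements the first-order expression above and
`within_bias_sim()` is an independent brute-force oracle: many
independent series, each demeaned by its own sample mean, pooled
cross-products. The pooled (ratio-of-sums) estimator is the relevant
one — the per-series estimator has a distinctly larger small-sample
bias, a mean-of-ratios versus ratio-of-sums distinction that is easy to
trip over. The two oracles agree to better than 0.01 for $T \ge 20$,
and the approximation is honest about its range: at $T = 3$, $\phi = 0$
the pooled estimator's expectation is $-0.5$.

## What the simulators emulate — and what they do not

The generators produce balanced Gaussian panels: equally spaced,
complete series with Gaussian innovations and Gaussian random effects.
That matches the Monte-Carlo designs whose results the package
reproduces, and isolates the centering mechanism from everything else.
Real diary data add missingness, unequal spacing, measurement error,
floor/ceiling effects and non-Gaussian level-2 distributions; none of
these are modelled, so passing tests demonstrate the centering bias
mechanism, not robustness of any estimator on field data. Time-varying
inertia and non-Gaussian innovations are likewise out of scope.

Defaults follow the study conditions throughout: $\phi = 0.3$,
$N = 100$, $T = 20$; within- and between-cluster predictor variances of
1 and within-slope 0.3 vs between-slope 1 for the standard model;
$\sigma^2_e = \sigma^2_{u0} = 3$, $\sigma^2_{u1} = 0.01$ for the
random-inertia grid.

## Numerical and design choices

* **Initial condition.** Each series starts from its stationary
  distribution $a_{1i} \sim N(0, \sigma^2_e/(1-\phi_i^2))$ — the model
  is explicitly stationary, so no burn-in is needed or used.
* **Boundary draws.** $\phi_i$ draws with $|\phi_i| \ge 1 - 10^{-6}$
  are redrawn jointly with $u_{0i}$ and counted
  (`attr(panel, "phi_redraws")`). At the dispersions studied
  (`sd_phi` $\le$ 0.11) redraws essentially never occur, so the
  truncation is cosmetic.
* **Random-effect covariance.** The grid designs set
  $\sigma_{u0,u1} = 0$ (only variances are specified there); the
  covariance is exposed as `cov_mu_phi` for users who want it.
* **Level-2 predictor design.** The cross-level study fixes
  var$(z) = 0.01$ (numerically safe next to var$(\phi_i) \approx
  0.01$), $\gamma_{11} = 0.4$, $\phi = 0.3$. The remaining constants
  are not pinned down by the stated correlations alone; taking
  var$(\mu_i) = 3$ from the random-inertia grid gives
  $\gamma_{01} = 0.37\sqrt{3}/0.1 \approx 6.408$ and residual variances
  $2.589$ and $0.01$, which reproduce all three target correlations
  (0.37, 0.37, 0.14) to two decimals. These are `ar_design_z()`
  defaults, overridable.
* **Which variance factor varies in the AR grid.** One study lists
  settings \{1, 3, 9\} that can be read as either $\sigma^2_{u0}$ or
  $\sigma^2_e$; `run_table(3, vary =)` exposes both readings, defaults
  to the table-header reading ($\sigma^2_e$), and a test confirms the
  inertia estimates are empirically invariant to the choice (the AR
  slope is scale-free in $\sigma^2_e$ and unaffected by the level of
  $\mu_i$).
* **Estimation.** REML by default (ML by argument) via `lme4::lmer()`;
  fixed-effect CIs are Wald, $\pm 1.96\,$SE. A singular unstructured
  random-effect covariance triggers one refit with independent random
  effects (flagged); convergence failures are flagged, excluded from
  Monte-Carlo summaries, and counted. Coverage denominators are
  converged fits only.
* **Lag centering constant.** The CMC constant for the lagged
  predictor is the cluster mean of *all* T outcome values — the sample
  analogue of $\mu_i$ and the applied-practice choice — not the mean
  of the T−1 lagged values. The difference is $O(1/T)$; consequently
  the centered *lagged* predictor has within-cluster mean near but not
  exactly zero (asserted as $\le 2\,\mathrm{range}/T$ in tests), while
  a centered non-lagged predictor is exactly zero-mean within cluster.
* **Grand mean for GMC** is the unweighted mean over analysis rows;
  with balanced panels weighting is moot.
* **Seeding.** Replication $r$ of a condition uses
  `base_seed + r`; each cell of a table grid offsets the base seed by
  `10000 * cell`. Any single replication is reproducible in isolation.

## Monte-Carlo reporting

`run_condition()` fits every requested scheme to the *same* simulated
panel within a replication, so scheme contrasts are paired and sharper
than the marginal Monte-Carlo standard errors suggest. Every summary
row carries `mc_se` (SD over replications / $\sqrt{reps}$) so that any
comparison against a reference value can be made at a principled
tolerance. Replication counts are configurable everywhere; the
package's own test suite runs the OLS-only studies at 300–1000
replications and mixed-model cells at 60–300, and the bundled
`scripts/acceptance.R` uses 1000 for OLS studies and small-N cells and
200–300 for the heavier mixed-model cells.

## Worked pipeline

```{r pipeline, eval = FALSE}
des <- ar_design(phi_mean = 0.3, sd_phi = 0.1, var_mu = 3, var_e = 3)
panel <- simulate_ar(des, seed = 1) |> build_lag()

# the two fits the dual-reporting advice needs
nc  <- panel |> apply_centering("lag_y", "NC") |>
  fit_lmm("lag_y_c", random_slope = TRUE)
cmc <- panel |> apply_centering("lag_y", "CMC_sample") |>
  fit_lmm("lag_y_c", random_slope = TRUE)
tidy(nc); tidy(cmc); transform_nc_params(nc)

# a Monte-Carlo cell, and the analytic expectation of its CMC bias
run_condition(des, schemes = c("NC", "CMC_sample"), reps = 200,
              base_seed = 7)
within_bias_approx(0.3, 20)
```

## Known limitations

The package quantifies the centering bias; it does not correct it.
Bias-corrected dynamic-panel estimators (half-panel jackknife,
analytical corrections) are a natural extension, as are measurement
error and unequal spacing, both of which further attenuate inertia
estimates on real data. Kenward–Roger/Satterthwaite degrees of freedom
and profile-likelihood or bootstrap intervals are deliberately not
implemented; Wald intervals are part of the studied procedure, and
coverage findings should be read with that in mind.
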