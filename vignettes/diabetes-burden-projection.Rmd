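---
title: "Projecting the adult diabetes burden: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting the adult diabetes burden: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

diabproj projects the burden of diabetes in an adult population over a
multi-decade horizon. Two pieces of machinery interact: a Bayesian
logistic growth model that forecasts the annual incidence of *diagnosed*
diabetes under low, middle, and high scenarios, and a family of annual
difference-equation compartment models that propagate the population
through the states *no diabetes* (X), *undiagnosed diabetes* (Z), and
*diagnosed diabetes* (Y) while staying exactly consistent with an
external demographic projection. This vignette documents the model, the
defaults, and the design decisions a maintainer would want explained.

## The incidence growth model

The observed series is the annual diagnosed-diabetes incidence rate
$y_t$ (per person-year, decimal scale) with reported standard error
$s_t$, for $t = 1, \dots, n$ (in the US application $t = 1$ is 1980 and
$n = 28$ is 2007). The model is

$$y_t \sim \mathrm{Normal}(\mu_t + \varepsilon_t,\; s_t^2), \qquad
  \mu_t = \frac{\rho}{1 + e^{-(\lambda_0 + \lambda_1 t)}},$$

a three-parameter logistic trend with asymptote $\rho$ plus a
stationary process error $\varepsilon_t$. Four error structures are
supported: unstructured (i.i.d.), AR(1), MA(1), and ARMA(1,1); AR(1) is
the default. Treating $s_t$ as known measurement error and
$\varepsilon_t$ as process error reconciles the two stated components
of variation, and is a configurable interpretation (`error_structure`,
and the AR process applies to raw rather than standardized residuals).

The asymptote bounds long-run incidence, so its prior carries real
subject-matter content: a log-normal with its central 95% (or 98%, as a
sensitivity analysis) probability mass between a contemporary
population rate (default 0.0078/yr) and the highest rate recorded in
any subpopulation (0.025/yr, the Pima Indians). Log-normality was
chosen because two quantile anchors exactly determine its two
parameters on positive support. $\lambda_0, \lambda_1$ get diffuse
normal priors (sd 100); $\phi, \psi$ are uniform on $(-1, 1)$; the
innovation sd $\sigma$ gets a half-normal prior with scale 0.01 on the
rate scale — an order of magnitude above any plausible surveillance
process error, so effectively weakly informative. All are configurable
through `mcmc_control()` and `build_rho_prior()`.

### Posterior computation

The error process is integrated out analytically: marginally
$y \sim \mathrm{MVN}(\mu(\rho, \lambda_0, \lambda_1),\,
\Sigma_\varepsilon + \mathrm{diag}(s^2))$ with $\Sigma_\varepsilon$ the
closed-form stationary autocovariance of the chosen error structure.
The sampler therefore works on a 4–6 dimensional marginal posterior.
Two numerical choices matter:

* **Parameterization.** The natural coordinates
  $(\log\rho, \lambda_0, \lambda_1)$ exhibit a strong banana-shaped
  ridge, because the data pin down the fitted curve while the asymptote
  is identified mainly by its prior. Sampling instead in
  $(\log\rho, \log\mu_1, \log\mu_n)$ — asymptote plus the two endpoint
  means, with the exact Jacobian — makes the posterior nearly
  orthogonal.
* **Kernel.** Each chain runs an adaptive random-walk Metropolis whose
  proposal covariance is adapted to the chain history and whose scale
  is tuned toward the multivariate optimal acceptance rate (~0.234)
  during warmup, then frozen. During sampling, 20% of proposals come
  from a shared independence kernel — a multivariate t (df = 4) fitted
  to the pooled warmup draws of all chains — which regenerates chains
  after excursions into the heavy near-unit-root tail of the AR
  coefficient and lets chains move between posterior regions in
  proportion to mass.

Convergence is summarized by the rank-normalized split-$\hat R$
(Vehtari et al. 2021, *Bayesian Analysis* 16(2)) on the natural
parameters, with the conventional threshold $\hat R \le 1.01$; the
classic statistic is noisy under the heavy AR tail. Defaults are 4
chains with 10,000 warmup and 10,000 kept iterations each (a fit takes
roughly ten seconds); exceeding the threshold raises a classed warning
with diagnostics attached, never a silent success. A smaller
independent MCMC engine (JAGS, via rjags) is used in the test suite as
a cross-check on a fixture where both samplers converge cleanly.

Projections $\mu_t$ for future years are computed per retained draw
from the logistic trend (so every projected path respects
$\mu_t < \rho$ and is monotone when $\lambda_1 > 0$). The three
scenarios are the pointwise 2.5th percentile (*low*), posterior mean
(*middle*), and 97.5th percentile (*high*) of those draws.

Error structures are compared by the posterior mean residual sum of
squares, with residuals $y - \mu - \hat\varepsilon$ and
$\hat\varepsilon$ the conditional mean of the error process given the
data and the draw. Among structures within 5% of the best, the fewest
parameters win, so AR(1) is preferred over ARMA(1,1) when the two are
indistinguishable.

## The compartment models

All rates are annual; flows occur during year $t$. The three-state
transition matrix, applied to start-of-year stocks, has rows

* X: stay $1 - \gamma - (\xi_1 + \xi_2)\beta$, to Z $\xi_2\beta$, to Y
  $\xi_1\beta$, dead $\gamma$;
* Z: stay $1 - r_1\gamma - \beta$, to Y $\beta$, dead $r_1\gamma$;
* Y: stay $1 - r_2\gamma$, dead $r_2\gamma$ (no remission).

Here $\gamma(t)$ is the nondiabetic death rate, $r_1, r_2$ the constant
relative risks of death for undiagnosed and diagnosed diabetes
(published sets: low mortality risk 1.77/2.11, high 1.00/4.08), and
$\beta(t)$ the undiagnosed-to-diagnosed rate. The matrix is applied as
simultaneous competing risks — deaths and disease transitions drawn
from the same start-of-year stock — rather than sequentially; this
keeps the row entries exactly the nominal rates and makes total deaths
exactly $\gamma(X + r_1 Z + r_2 Y)$. After transitions, the new
18-year-old cohort $b(t)$ enters X (all nondiabetic), and net migration
$m(t)$ is allocated across states in proportion to start-of-year
shares.

**Census consistency.** Given the demographic identity
$N(t) = N(t-1)(1 - d(t)) + b(t) + m(t)$, requiring total model deaths
to equal $d(t)N(t-1)$ pins down
$\gamma(t) = d(t)N(t-1)/(X + r_1 Z + r_2 Y)$ — the unique choice under
constant relative risks. With that, $X + Z + Y = N(t)$ holds to
floating-point exactness every year, which the tests assert at relative
1e-9 across the full horizon.

**Calibration of $\xi_1, \xi_2, \beta$.** The diagnosed share of new
diabetes cases, $\eta = \xi_1/(\xi_1 + \xi_2)$, is assumed constant.
Its default value comes from the undiagnosed-duration argument: if 95%
of people spend less than 7 years undiagnosed and the diagnosis hazard
$h$ is constant, then $h = -\ln(0.05)/7 \approx 0.428$, the six-month
diagnosis probability is $1 - e^{-h/2} \approx 0.19$, and the
within-first-year probability $1 - e^{-h} \approx 0.348$ is taken as
$\eta$ — a new case counts as diagnosed at onset if diagnosed within
its first model year. At the base year, three constraints determine
$(\xi_1, \xi_2, \beta)$: total new-diabetes flow from X equals
$I \cdot X$ (with $I$ the total-diabetes incidence among nondiabetics,
0.0106/yr from the glycemic-subgroup calibration), observed diagnosed
incidence over the at-risk pool equals $i$ (0.0084/yr), and the
$\eta$ identity. In later years $\beta(t)$ is re-solved from the
diagnosed-incidence identity
$\xi_1\beta X + \beta Z = i(t)(X + Z)$ with $i(t)$ the scenario rate.

**Four-state split.** The nondiabetic pool is split into a high-risk
stratum HX (prediabetes — impaired fasting glucose in the default
calibration, share $p = 0.257$) and low-risk LX, with stratum
incidences in the constant ratio $c$ (high/low). From the published
high-risk incidence $\lambda = 0.0287$/yr,
$c = \lambda / [(I - p\lambda)/(1-p)] = 6.6$. Inter-strata flows keep
$p(t)$ constant: a fraction $q = 0.93$ of the surviving nondiabetic
high-risk stock is retained (so the high-risk retention probability is
$\alpha_1(t) = q(1 - \gamma - \lambda_H)$, about 0.90 in the base
year), and the balancing inflow from LX is solved each year. The
marginal X, Z, Y then reproduce the three-state trajectory to
floating-point accuracy, which the tests assert.

**Five-state intervention.** The high-risk stratum becomes the
intervention group IX whose incidence is scaled by $1 - \nu$; coverage
times efficacy gives the effective reduction (0.5 × 0.5 = 0.25 by
default). A new state LXI holds intervention participants who regressed
to low risk (low-risk incidence, initial value 0, inflow at
`regression_rate`, default 0 — no published value exists for that
rate). The transition rates $\beta, \lambda_H, \lambda_L$ are taken
from the no-intervention baseline run — the intervention scales the
incidence the baseline population experienced — while $\gamma(t)$ is
re-back-calculated along the intervention trajectory so census
consistency continues to hold. Recomputing $\beta$ self-consistently
would let the imposed diagnosed-incidence scenario partly offset the
intervention; with baseline rates, the first-year prevented share is
exactly $\nu\, p\, c / (pc + 1 - p) \approx 0.17$. With $\nu = 0$ and
no regression the five-state model reproduces the four-state model
identically.

Counts are continuous expected values, not integers. Tables report
millions (population stocks) or thousands (incident cases) rounded
half-away-from-zero to one decimal; rounding is presentation-layer
only.

## The synthetic study conditions

The real inputs behind the original US analysis (the Census projection
files and the national surveillance incidence series with standard errors) were never
archived, so the package ships a synthetic-data module reproducing
their statistical structure; every parameter below is a fixed study
condition, not a tuning knob.

* **Census:** adult population anchored at 215,750,418 (2007) rising
  through the printed five-year totals to 306.3M (2050), interpolated
  with a monotone Hyman spline; death rate declining linearly from
  0.0090 to 0.0078/yr; constant net adult migration of 1.0M/yr. The
  18-year-old cohorts are back-derived so the census recursion holds
  exactly (about 3.6–4.0M/yr, the realistic order). Death rates,
  migration and cohort sizes are aggregate abstractions — the real
  files are age-structured.
* **Incidence series:** $\rho = 0.018$, $\lambda_0 = -1.54$,
  $\lambda_1 = 0.0454$, chosen so the noise-free curve passes through
  the published 1980 rate (3.3/1,000), the 2007 rate (7.8/1,000), and
  reaches ~14.7/1,000 by 2050; AR(1) deviations with $\phi = 0.6$,
  $\sigma = 2 \times 10^{-4}$; standard errors
  $0.0042\sqrt{\mu_t}$ (≈3 per 100,000 at current rates) with mild
  jitter. The generator deliberately draws no separate measurement
  noise — the series is trend plus process error — so recovery tests,
  fitted with the measurement term included, are conservative. Where a
  test needs data from the fitted model's own observation process
  (e.g. the residual-whiteness check), the measurement draw is added
  explicitly.
* **Initial state:** prevalences 0.0535 undiagnosed / 0.0765 diagnosed
  in 2007, consistent with the published 2010 stocks.

What passing tests on these conditions shows: the machinery is
internally exact (conservation, marginalization, calibration
identities) and the inference is well calibrated against its own
generative model. What it does not show: agreement with the original
published table values, which depend on the unarchived age-structured
inputs; the package reproduces their qualitative pattern (prevalence
roughly doubling 2010–2050 under middle incidence, intervention
preventing ~16–18% of incident cases early on) but not their exact
numbers, and the headline published quantities that *are*
desk-reproducible (the calibration constants) are reproduced exactly.

## Degenerate inputs and failure modes

Infeasible configurations fail loudly with classed errors: death rates
implying $\gamma r_2 \ge 1$ (`mortality_overflow`), negative implied
birth cohorts (`infeasible_profile`), transition rows with negative
stay probability naming the year (`infeasible_rates`), strata
rebalancing outside the available stock (`infeasible_strata`),
calibration constraint systems without a positive solution
(`infeasible_calibration`). Zero incidence is allowed ($\beta = 0$);
$\nu$ may be 1 (total prevention limit). MCMC non-convergence warns
(class `convergence_warning`) and attaches diagnostics rather than
failing.

## Known limitations

The model is aggregate: no age, sex, or race/ethnicity structure, and
no feedback of prevalence on incidence or detection. Relative risks of
death are constant over time. Migration carries the prevalence of the
resident population. The five-state matrix is the minimal faithful
extension of the four-state model; its regression flow is isolated
behind `regression_rate` for future refinement. Literature constants
0.398 and 0.129 connected to the original births/migration allocation
are carried in the calibration set for provenance but are not
independently derivable and the default allocation (all births
nondiabetic, migration proportional) does not use them.
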