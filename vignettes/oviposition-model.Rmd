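---
title: "An age- and temperature-structured oviposition model for the beet leafhopper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An age- and temperature-structured oviposition model for the beet leafhopper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovitherm)
```

## The model

The beet leafhopper (*Circulifer tenellus*) is the North American vector of
beet curly top virus. Damaging spring populations build up on
non-agricultural host plants, so quantifying how many eggs a female lays on
each host, and when, is the basis for predicting population growth outside
crop fields. `ovitherm` implements the standard four-component decomposition
of insect oviposition under fluctuating temperature:

1. **Temperature-dependent total fecundity.** The expected lifetime egg
   total of a female held at constant temperature $T$ follows a Gaussian
   thermal performance curve,
   $$f(T) = R_m \exp\!\left[-\tfrac{1}{2}\left(\frac{T - T_{max}}{k}\right)^2\right],$$
   with $R_m$ the maximum total fecundity (eggs/female), $T_{max}$ the
   thermal optimum (°C) and $k$ a steepness scale (°C). $R_m$ doubles as the
   host-suitability index: hosts share $T_{max}$ and $k$ and differ in
   $R_m$.
2. **Temperature-dependent female aging rate.** Adult females age at rate
   $r(T) = \sigma\, e^{a + bT^{2.5} + cT^{3}}$ (1/day), where $\sigma$ is a
   host multiplier ($\sigma = 1$ on sugar beet, the rearing baseline).
   Summing the daily rate from adult emergence gives *normalized
   (physiological) age* $Px$; one unit of $Px$ is roughly a full adult
   lifespan.
3. **Age-specific cumulative oviposition.** The fraction of the lifetime
   total laid by age $Px$ follows a Weibull curve
   $p(Px) = 1 - e^{-(Px/\alpha)^\beta}$. Because age is normalized, data
   from all temperatures and hosts pool onto one curve.
4. **Age-specific survival.** The fraction of females alive at age $Px$ is
   a sigmoid $s(Px)$ with $s(\gamma) = 0.5$.

Daily expected oviposition on day $i$ of adult life is the product
$f(T_i)\,[p(Px_{i+1}) - p(Px_i)]\,s(Px_i)$; weekly values are 7-day sums.
The shipped parameter bundle (`default_host_models()`) carries the fitted
values for sugar beet and four non-agricultural hosts (*Erodium
cicutarium*, *Kochia scoparia*, *Plantago ovata*, *Salsola tragus*).

```{r bundle}
hosts <- default_host_models()
sapply(hosts, function(h) c(R_m = h$fecundity$r_m, sigma = h$aging$sigma))
```

## The survival parameterization

The printed slope of the fitted survival sigmoid is $\delta = -5.083$. Read
literally as $s(Px) = 1/(1 + e^{(\gamma - Px)/\delta})$, the curve starts at
only $\approx 0.55$ at emergence — incompatible with the near-complete early
survival the underlying weekly records show, and with common sense for
week-old adults. Read as a multiplicative slope,
$s(Px) = 1/(1 + e^{(Px-\gamma)\lvert\delta\rvert})$, the same numbers give
$s(0) \approx 0.995$ and $s(\gamma) = 0.5$ exactly. Both parameterizations
are implemented (`survival_params()`); `slope_multiplier` is the default
because it reproduces both anchor facts (50% survival at $\gamma$,
near-complete survival at emergence). Every downstream result that uses
survival (simulation, death-time sampling) honours the chosen
parameterization.

## Fitting

`fit_fecundity()`, `fit_aging()`, `fit_schedule()` and `fit_survival()`
estimate the four components by Levenberg–Marquardt least squares
(`minpack.lm`), with standard errors from the Jacobian at the optimum and
adjusted $r^2$ as the fit summary. Numerical choices worth knowing:

* **Aging is fitted in rate space**: observed rates are reciprocals of
  individual longevities in days (weekly records are converted at the
  fitting boundary, ×7), and squared *rate* error is minimized. Starting
  values come from the exact linear regression of log rate on $T^{2.5}$ and
  $T^{3}$.
* **The Gaussian fecundity fit is unconstrained** in $(R_m, T_{max}, k)$;
  since the curve is symmetric in the sign of $k$, the fitted $k$ is
  reported as $\lvert k\rvert$. Starting values: $R_m$ at the largest
  observation, $T_{max}$ at the temperature with the largest mean (smallest
  such temperature on ties), $k$ at half the observed temperature range.
  Runs whose $k$ diverges are reported as unidentifiable rather than
  returned.
* **Constrained one-parameter refits are closed form.** The host comparison
  refits only $R_m$ (fixed $T_{max}, k$) or only $\sigma$ (fixed $a,b,c$),
  both linear least-squares problems:
  $\hat R_m = \sum w_i g_i y_i / \sum w_i g_i^2$ and
  $\hat\sigma = \sum \hat r_i y_i / \sum \hat r_i^2$. The package solves
  them exactly (tests cross-check against a generic 1-D minimizer).
* Iterative fits use relative tolerances of $10^{-12}$ and up to $10^4$
  function evaluations; there are no stochastic restarts.

Refitting $R_m$ on the published per-condition mean totals (two
observations per host, 30 and 35 °C, unweighted) reproduces the published
host $R_m$ values to within about 2%; the residual gap exists because the
original fits used raw per-female data that were never published. Replicate
counts can be supplied through `weights` when means of unequal groups are
combined.

The $\sigma$ refits deserve a caveat: the published per-host $\sigma$
values are not reproducible from the published longevity means combined
with the baseline aging curve (they were evidently fitted to individual
reciprocal longevities that are unavailable). $\sigma$ estimation is
therefore validated by identity and recovery properties — proportional
rates return the exact ratio; noisy synthetic designs return the generating
$\sigma$ without bias — not against the printed per-host values.

## Simulation

`simulate_oviposition()` runs the model under any complete daily series;
`temperature_sweep()` runs constant temperatures 10–50 °C. Conventions
(each is a deliberate choice where the model description is silent):

* $Px$ is computed at day boundaries, starting at 0 on the emergence day;
  one daily mean drives the whole day. Sub-daily integration is out of
  scope.
* Survival multiplies each day at the *start-of-day* age; the difference
  from midpoint evaluation is far below validation noise.
* "Week $n$" means days $7(n-1)+1 \ldots 7n$ of adult life; a trailing
  partial week is flagged, so weekly sums always repartition daily values
  exactly.
* Survival weighting defaults **on** — that is the form comparable to
  cohort observations — and can be disabled, in which case the constant-
  temperature lifetime total telescopes exactly to $f(T)\,p(Px_{end})$
  (machine-precision conservation, which the tests assert).
* Temperatures outside [0, 50] °C warn (extrapolation) but are not clipped.
* Sweep horizon: until $p(Px) > 0.9999$ or 30 weeks.

Two different summaries answer "at which temperature is weekly laying
greatest". The maximum weekly value over all weeks peaks near 33 °C, where
the *second* week of adult life happens to straddle the mode of the laying
schedule. The *first-week* value, which isolates temperature's effect on
early-life laying from that week-alignment artifact, peaks near 37.5 °C —
the hot-shifted behavior reported for this system. The sweep reports both
(`peak_weekly`, `first_week`).

```{r sweep}
sw <- temperature_sweep(hosts$sugar_beet, temps = seq(10, 50, 5))
sw$summary
```

The oviposition period (weeks until 99% of the schedule is complete)
lengthens monotonically as temperature falls — cool females age slowly and
spread the same schedule over more calendar weeks.

## The synthetic bioassay generator

No raw per-female cage data were ever deposited for this system, so
`generate_bioassay()` emulates the weekly cage bioassay from a parameter
bundle: $n$ females per host × regime (11–15 in the original design, at
constant 30 or 35 °C, plus 10–15-week fluctuating winter/summer regimes),
weekly egg counts and alive/dead status per female. Components:

* **Death times** are drawn by inverse-CDF sampling of the survival curve
  (lifetime CDF $1 - s(Px)$) and converted to days through the aging
  trajectory. Death is recorded in the week containing the death day; eggs
  laid in the death week up to the death day are included. Alive flags are
  monotone by construction.
* **Count noise** defaults to negative binomial (dispersion 5): the
  published condition SDs exceed Poisson expectation, consistent with the
  negative-binomial GLMM originally used for the totals. Poisson and
  noise-free (expectation) modes are available. Mating failure and
  counting error are absorbed into the count noise rather than modeled.
* **Fluctuating regimes** (`generate_regime()`) are mean + one-cycle
  sinusoid + daily Gaussian noise, truncated at 0 °C. The winter semi-field
  defaults (12 °C mean, amplitude 4, noise SD 2 °C, 105 days) and summer
  greenhouse defaults (28 °C mean, amplitude 3, noise SD 1.5 °C, 84 days)
  are *assumptions* — plausible logger summaries for the two validation
  settings, not published records.

### Realized versus potential fecundity

One structural subtlety dictates a generator option. The fecundity curve
$f(T)$ is fitted to *realized* lifetime totals of females that died
naturally mid-schedule; yet the simulator multiplies $f$ by survival again.
Under the fitted schedule and survival curves a female completes on average
only $E[p(Px_{death})] \approx 0.92$ of her schedule
(`schedule_completion()`), so the two readings of $f$ differ by ~8% and no
single generator can satisfy both:

* `fecundity_basis = "realized"` (default): per-female laying intensity is
  scaled by $1/0.92$ so that the *mean observed total* equals $f(T)$ —
  matching what condition-mean totals measure. Use this when the generated
  data will be refitted: fecundity refits are then unbiased (the test suite
  demonstrates mean $\hat R_m$ within a fraction of a percent of truth over
  hundreds of replicate bioassays at the original sample sizes).
* `fecundity_basis = "potential"`: the literal forward model — intensity
  $f(T)\,\Delta p$, truncated at death, so long-lived females approach
  $f(T)$ and the survival-weighted simulator matches the generated cohort
  exactly (closed-loop validation bias under 1%).

Validating survival-weighted predictions against *realized*-basis data
shows a systematic ~8% underprediction. That is not a bug of either side:
it is the double-counting of mortality inherent in fitting $f$ to realized
totals and then multiplying by survival, and it parallels the tendency of
this model family to underestimate observed oviposition in semi-field
validation.

## Validation

`validate_model()` predicts weekly oviposition per *original* female
(survival weighting on) and compares against observed weekly means on the
same cohort basis — dead females contribute zeros, since whether observed
means are per-cohort or per-survivor is not otherwise determined. The
report holds RMSE (eggs/week), $r^2$ (squared Pearson correlation of paired
weekly values) and mean bias (predicted − observed); that minimal statistic
set is this package's choice. Closed-loop checks (generate from a bundle,
predict with the same bundle) reach $r^2 > 0.99$ at 500 females, and an
inflated-fecundity generator produces the expected negative bias.

## What the synthetic tests do and do not show

Passing recovery tests show the estimators are consistent and unbiased
*under the model's own assumptions*: independent females, stationary
count-noise, exact weekly censoring, temperature as the only driver. Real
cage data add male replacement effects, leaf-quality variation, staining
and counting error, and between-cage microclimate — none of which the
generator emulates as distinct processes. Agreement on synthetic data
therefore validates the software and the estimation procedure, not the
biological adequacy of the model for any new host or setting.

## Problem sizes

The shipped test suite uses the original bioassay scale (11–15 females per
condition) for closure experiments with 300 replicate bioassays, 200-female
designs for single-fit recovery, 500 females for closed-loop validation,
and 1 °C sweep grids — sizes at which all Monte-Carlo acceptance bands are
comfortably resolved while the whole suite runs in well under a minute.

## Known limitations

* Immature development, male biology, and virus transmission are out of
  scope; the model starts at adult female emergence.
* The aging-rate curve is an extrapolation outside roughly 10–40 °C; the
  package warns outside [0, 50] °C but does not refuse.
* Day resolution: thermoperiod within a day is invisible to the model.
* The literal-slope survival form is retained for fidelity but yields a
  biologically implausible 45% instantaneous early-life mortality; prefer
  the default parameterization.
* Host bundles assume the oviposition schedule and survival curves are
  host-invariant (they were fitted on data pooled across hosts and
  temperatures); only $R_m$ and $\sigma$ carry host differences.
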