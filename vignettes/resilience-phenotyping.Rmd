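---
title: "Resilience phenotyping from daily milk yield: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience phenotyping from daily milk yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilmilk)
library(dplyr)
```

## The problem

Dairy cows differ in how strongly disturbances — disease episodes, heat
waves, feed changes — show up in their milk production, and in how quickly
they recover. With automated milking systems recording daily milk yield
(DMY) for every cow, those responses can be phenotyped at scale: a cow whose
production runs smoothly along her lactation curve, with few and shallow
perturbations, is coping well with whatever her environment throws at her.

`resilmilk` turns raw per-day milk records of first-parity cows into 40
named *sensor features and resilience indicators* per lactation, and
compares them across breed groups and across herd groups that differ in
their share of Holstein-Friesian (HOL) genetics. Because real herd-recorded
data of this kind is proprietary, the package ships a synthetic-data
generator with known ground truth, so that every stage of the pipeline is
testable end to end.

## Per-lactation models

Two curves are fitted to each eligible lactation (at least 100 recorded
days, first record within 5 days of calving, no gap longer than 5 days,
calving year 2010 or later):

* **Wood curve**, $\mathrm{DMY} = a\,\mathrm{DIM}^{b} e^{-c\,\mathrm{DIM}}$,
  fitted by nonlinear least squares on *all* data (days $\ge 1$),
  perturbations included. It describes the lactation as it happened: peak
  yield and day, slopes to and from the peak, cumulative 50- and 305-day
  yields (category 1), and the variability of its residuals (category 2).
  Initial values come from ordinary least squares on the log-linearised
  model; Levenberg-Marquardt refinement enforces $a>0$, $c\ge 0$. On
  noise-free inputs the generating parameters are recovered to about
  $10^{-6}$ relative; the log-linear start makes the fit deterministic.
* **Expected lactation curve**: a fourth-order polynomial quantile
  regression of DMY on DIM, fitted on days 11–340 at conditional quantile
  $\tau = 0.7$. Because the curve sits at the 70th percentile, it estimates
  the *unperturbed* production level: dips pull ordinary mean fits down,
  but a 0.7-quantile fit stays near the upper envelope. Its residuals
  drive categories 3–6: curve dynamics, residual statistics, perturbation
  features, and the two resilience indicators — `LnVar` (natural log of the
  residual variance) and `ExpAClag1` (lag-1 autocorrelation of residuals,
  computed over truly consecutive-day pairs only, so data gaps never
  fabricate correlation).

### Fitting the quantile curve

The pinball (check) loss $\sum_t \rho_\tau(y_t - p(x_t))$ is minimised by
iteratively reweighted least squares with an annealed smoothing floor on
$|r_t|$ ($10^{-2} \to 10^{-8}$, up to 60 iterations per stage, OLS start).
The procedure is deterministic — no random restarts — and on test problems
it agrees with exact linear-programming solutions to about $10^{-7}$ in
predictions. Internally the polynomial uses $x = \mathrm{DIM}/100$ for
conditioning; coefficients are reported on the raw day scale, and
predictions are clipped at 0 kg because unconstrained quartics can go
negative outside their support.

For population-scale runs, `extract_features(quantile_fit = "fast")` fits
all lactations at once on the shared 11–340 day grid: unobserved days get
weight zero (which removes them from the weighted normal equations
exactly), and each IRLS iteration reduces to two dense matrix products plus
a $5\times 5$ Cholesky solve vectorised across cows. With a fixed
four-stage annealing schedule (15 iterations per stage) the batched
solution typically differs from the fully converged per-lactation fit by
less than 0.05 kg in predictions (worst cows ~0.5 kg near the window
edges); the package defaults to the exact fit and leaves the batched mode
as an explicit choice.

### A known limitation of the quartic

A fourth-order polynomial cannot follow the steep early-lactation rise of a
Wood-shaped curve: even its least-squares approximation errs by 2–5 kg in
the first ~2 weeks of the fitting window, and the asymmetric quantile loss
widens this. The artifact is inherent to the expected-curve model itself
(any analysis using this curve shares it), it affects all lactations
alike, and it is one reason group comparisons — not absolute per-cow values
— are the intended use. Detection-logic tests therefore use base curves the
quartic can represent exactly, so that detector correctness is not
confounded with curve-approximation error.

## Perturbations

A *perturbation* is a maximal run of at least 5 consecutive observed days
below the expected curve **that reaches below 85% of the expected
production on at least one day**. It is *major* when it holds at least 5
successive days below the 85% line, otherwise *minor*. Two points deserve
explanation:

* **Why the 85% qualification?** The 0.7-quantile curve leaves roughly 70%
  of all days with (mostly tiny) negative residuals, so runs of five or
  more slightly-negative days are ubiquitous and carry no information about
  disturbances — they are ordinary variation and are counted separately by
  the residual feature `ExpNeg_5d`. Requiring a genuine drop below 85%
  separates episodes driven by an actual disturbance from quantile-side
  noise; without it, the episode count is insensitive to the true
  perturbation rate (injected dips merely merge into existing runs), and
  the count and `ExpNeg_5d` would be the same number by construction even
  though they measure different things.
* **Numerical guard.** A day counts as "below the curve" only when its
  residual is below $-10^{-3}$ kg (one gram of milk). This prevents
  floating-point-level offsets between data and fitted curve from forming
  multi-day "episodes" on noise-free data; one gram is far below the
  resolution of any milk meter.

Each episode records its boundaries, the deepest day (earliest day of
maximum deficit on ties), development days (start to deepest, inclusive)
and recovery days (deepest to end, so development + recovery = duration),
the summed milk loss in kg, and the deficit at the deepest day.

## The 40 features

`feature_catalog()` lists all names, categories, units and definitions.
Counts per category are 6 (Wood-curve dynamics), 6 (Wood residuals), 4
(expected-curve dynamics), 11 (expected-curve residuals), 11
(perturbations) and 2 (resilience indicators). The residual-statistic
categories were completed with standard summaries (RMSE, $R^2$, mean/max
residual, moment skewness, share of days below 70%/85% of expected, sign
changes) so that each category carries its full count; zero-filled
aggregates (e.g. no major perturbation means 0, not missing) keep the
downstream regressions complete-case without imputation.

## Group comparisons

Features and the average-DMY covariate are min-max standardised per
analysis, so coefficients are comparable across features. Two linear
models are fitted per feature:

* **Breed model**: intercept (the purebred-HOL baseline) + 11 breed
  proportions (1 for a purebred of the breed, 0.5 for a HOL crossbred) + a
  crossbred indicator (heterosis) + standardised average DMY (the
  milk-yield scaling effect: higher-producing cows vary more in absolute
  terms).
* **Herd model**: intercept + `SEL` (1 = herd with mean HOL fraction below
  0.50, 0 = at least 0.99; a positive coefficient means a higher value in
  low-HOL herds) + standardised average DMY, optionally restricted to
  purebred HOL cows to separate herd environment from breed composition.

Per feature, Cook's distance
$D_i = \frac{r_i^2}{p\,\mathrm{MSE}}\cdot\frac{h_{ii}}{(1-h_{ii})^2}$
(with $\mathrm{MSE} = \frac1n\sum(y_i-\hat y_i)^2$, the $1/n$ form) flags
the 0.5% most influential observations — those above the 99.5th
linear-interpolation percentile — which are removed before a single refit;
the removal is not iterated. Design columns that lose all variation after
removal (a rare breed whose few animals were all influential) are dropped
from the refit. Significance uses the Bonferroni threshold
$\alpha = 0.05/40 = 0.00125$ with strict inequality, and
`significance_summary()` reports, per model term and feature category, the
percentage of features with a significant coefficient.

Cohort construction mirrors the study design: purebreds carry at least 7/8
of one known breed, crossbreds are exactly half HOL and half one other
known breed; over-represented purebred Holsteins are down-sampled by four
rounds of sorting (age at first calving, average DMY, calving date, herd
mates) each followed by a uniform every-$n/k$-th draw — index scheme
$\mathrm{round}(i\,n/k)$, $i = 0..k-1$, collisions resolved by the next
free position — which covers the full range of every trait and is fully
deterministic (ties broken by id). Breeds with fewer than 10 animals are
dropped. Herd selection keeps 50–300-cow herds, labels them SEL50
(mean HOL fraction < 0.50) or SEL99 (≥ 0.99), keeps all SEL50 herds and
down-samples SEL99 herds to 180 with the same scheme on herd-level traits.

## The synthetic-data generator

`simulate_population()` generates herds of 50–300 cows with a configurable
mix of near-pure-Holstein and mixed-breed herds; cows get breed
compositions in eighths (8/8 or 7/8+1/8 purebreds, 4/8+4/8 crossbreds),
breed-scaled Wood curves (mean-yield anchors from ~27 kg for HOL down to
~15 kg for Groninger Whiteheaded; between-cow lognormal scale variation
with 10% CV), AR(1) day-to-day noise, sporadic multi-day perturbations, and
sporadic missing days. Key defaults and why:

* `sigma = 1.8` kg at the HOL reference level, scaled proportionally with
  each cow's expected mean yield — the same mean-variance scaling premise
  that motivates the aDMY covariate. An absolute noise sd would make
  85%-threshold crossings strongly yield-dependent, a confound that is not
  a feature of real data.
* `rho = 0.3` lag-1 noise autocorrelation: together with the perturbations
  this yields expected-curve residual autocorrelations around 0.3–0.45 and
  roughly 6–8 detected episodes per lactation with development plus
  recovery phases of one to two weeks — the order of magnitude reported
  for automated-milking data.
* `lambda = 3` perturbations per lactation, durations 5 days plus a
  geometric tail (mean ~12), multiplicative depth 0.5–0.95 of expected at
  the deepest day. The injected profile declines linearly over the
  development phase (~40% of the duration) and recovers exponentially,
  staying strictly below 1 throughout so the deepest day is unique and
  every episode day carries a positive deficit. Episodes are placed
  without overlap inside days 11–340 with a 2-day buffer so injected
  episodes never merge with each other.
* Lactation lengths 305–340 days, missing-day rate 0.005, first calvings
  2015–2020, age at first calving ~760 ± 60 days.

`truth_feature_oracle()` computes the category-5 features implied by the
injected ground truth analytically, applying the same qualification and
severity rules to the injected depth profile; on zero-noise simulations the
detected features match it exactly (a test asserts this).

**What the generator does not emulate:** genetics and pedigree structure
(breed effects are injected directly, e.g. per-breed perturbation-rate
multipliers, not inherited), seasonality and weather, management
interventions, milking-robot measurement artifacts, and nested
perturbations (episodes within episodes). Passing tests therefore show
that the pipeline recovers the structure this generator encodes — they do
not show that real herds satisfy that structure.

## Problem sizes and runtimes

The test suite exercises single lactations (330 days), populations of
60–2,000 cows for structural checks, and — for the end-to-end
effect-recovery check — 20 replicates of 20,000-cow populations (100 herds)
in which one breed's perturbation rate is halved; the breed coefficient on
the perturbation count is then expected to be negative and Bonferroni-
significant in at least 90% of replicates. The acceptance script repeats
the same computations with 10 replicates. Population-scale feature
extraction uses the batched quantile fit and the vectorised grid detector;
both are tested for agreement with the exact per-lactation route.

## Known limitations

* Breed and herd-environment effects are confounded by design: cows of
  different breeds live on different farms, so "breed" coefficients are
  combined breed-and-environment contrasts.
* The quartic expected curve misfits the first two weeks of the window
  (see above); features anchored there inherit a common bias.
* The herd model treats cows as independent; herd random effects are out
  of scope.
* Min-max standardisation is sensitive to extreme values; the
  Cook's-distance removal mitigates but does not eliminate this.
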