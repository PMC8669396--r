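---
title: "Modelling the longitudinal pattern of aerenchyma formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the longitudinal pattern of aerenchyma formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerofit)
```

## The biological problem

Rice adventitious roots survive flooded paddies by forming aerenchyma:
cortical cells die in a programmed way and leave gas-filled lacunae that pipe
oxygen from the shoot down to the respiring root apex. On a transverse
section the trait is quantified as the *aerenchyma percentage* — aerenchyma
area over cross-sectional area, times 100. Sectioning a root every 0.5 cm
from the apex yields a longitudinal profile of this percentage, which rises
sigmoidally from zero near the apex to a plateau in the mature zone. The
shape of that rise, and how it changes with root length, summarizes how fast
and where cortical cells are sacrificed.

`aerofit` models these profiles. Its pipeline is: fit competing sigmoid
families per root, select a winner by goodness of fit and bootstrap bias
diagnostics, read off biologically interpretable critical points from the
winner's derivatives, regress the winner's parameters on root length to get
a single length-aware model, and integrate that model into a whole-root
aerenchyma volume.

## Model families

Four three-parameter sigmoids compete, all mapping distance from the apex
$x$ (cm) to aerenchyma percentage $y$:

* Ti-Gompertz: $y = A\,e^{-e^{-B(x - C)}}$
* W$_0$-Gompertz: $y = A\,e^{-C e^{-Bx}}$
* logistic: $y = A / (1 + e^{C - Bx})$
* von Bertalanffy: $y = A (1 - C e^{-Bx})^3$

$A$ is the upper asymptote (%), $B$ a rate (cm$^{-1}$). The two Gompertz
forms are one curve under the exact reparameterization
$C_{\mathrm{Ti}} = \log(C_{W_0})/B$ (`gompertz_convert()`); the Ti form is
preferred because its $C$ *is* the inflection abscissa, where the curve
always sits at $A/e$ — 36.8% of the asymptote:

```{r}
p <- c(A = 33.34, B = 0.751, C = 2.824)
growth_curve("ti_gompertz", p, p[["C"]]) / p[["A"]]
```

The Ti-Gompertz derivatives up to third order are implemented analytically;
the logistic and von Bertalanffy third derivatives use a central difference
on the analytic second derivative (step $10^{-4}\max(1, |x|)$), since only
the Ti-Gompertz critical points feed the downstream biology.

## Fitting and model competition

`fit_profile()` minimizes least squares on the *per-position means* of the
replicate measurements (the study design measures each section 12 times;
means are what the sigmoid describes), via Levenberg–Marquardt with box
bounds $A \in (0, 100]$ (a percentage), $B \in (0, 50]$, and $C > 0$ where
the family's form requires it. The basal 1 cm of every root is excluded:
measured aerenchyma dips there for reasons unrelated to the apex-to-base
developmental wave, so those sections would distort the sigmoid. Convergence
requires one of the Levenberg–Marquardt stopping rules (relative
sum-of-squares, parameter, or gradient-orthogonality tolerance; gradient
tolerance $10^{-8}$, at most 2000 evaluations).

Starting values are heuristic but deterministic: $A_0 = 1.05 \max(\bar y)$,
the location from the abscissa where the means cross the family's
characteristic fraction of $A_0$ ($1/e$ for Ti-Gompertz, half for the
logistic), and $B_0$ from the slope of the log-linearized interior points,
clamped to $[0.05, 10]$.

Families are ranked by the least-squares information criteria
$\mathrm{AIC} = n\ln(\mathrm{SSR}/n) + 2p$ and
$\mathrm{BIC} = n\ln(\mathrm{SSR}/n) + p\ln n$ (`compare_models()`, ties by
BIC then SSR). An alternative AIC spelling, $n + \ln(\mathrm{SSR}/n) + 2p$,
appears in some reports; it is available as `variant = "printed"` for
comparability, but the standard form is the default because only it keeps
AIC and BIC on the same $n\ln(\mathrm{SSR}/n)$ scale.

One deliberate bound choice: von Bertalanffy's $C$ is *not* capped at 1.
Capping it forces $y(0) \ge 0$ but pins the long-root fits at the bound and
costs them roughly a point of $R^2$; unconstrained fitting (as in the usual
curve-fitting toolboxes) lets $C$ exceed 1, at the price of a slightly
negative predicted percentage right at the apex — a fitted-curve artifact,
visible and interpretable, rather than a silently degraded fit.

## Bootstrap bias diagnostics

Goodness of fit alone can pick a family whose parameters are badly
estimated. `residual_bootstrap()` resamples the mean-centered residuals onto
the fitted values 1,000 times (residuals, not $(x, y)$ pairs: the abscissae
are a fixed sectioning grid), refits from the OLS estimate, and reports the
percentile 95% interval, its width, the bias (bootstrap mean minus OLS
estimate) and the sample skewness of each parameter's replicate
distribution. `bias_report()` flags a parameter when its relative bias
exceeds 5% or its |skewness| exceeds 1 — skewness quantifies the "visually
asymmetric histogram" judgement reproducibly; both thresholds are
arguments. Refits that fail to converge are dropped and counted rather than
redrawn, keeping the replicate count interpretable; more than 50% failures
aborts.

## Critical points and formation stages

With $u = e^{-B(x-C)}$, the Ti-Gompertz third derivative is proportional to
$u^2 - 3u + 1$, whose roots $u = (3 \pm \sqrt 5)/2 \approx 2.618, 0.382$
give the maximum acceleration and deceleration points
$\mathrm{MAP}, \mathrm{MDP} = C \mp \ln\!\big((3+\sqrt5)/2\big)/B$,
symmetric about the inflection point $\mathrm{IP} = C$. The initial point
solves $y = 1$% (the detection floor of the sectioning assay):
$\mathrm{InP} = C - \ln\ln(A/1)/B$, and the near-plateau point solves
$y = 0.95A$: $\mathrm{MVP}_{95} = C - \ln(-\ln 0.95)/B$. A bisection oracle
on the analytic derivatives (`derivative_roots()`) verifies the closed forms
independently.

Points falling beyond the observable part of the root — abscissa greater
than $L - 1$ cm, the basal exclusion — are censored and reported as missing,
which reproduces exactly which entries short roots can and cannot report.
The inflection point is exempt from censoring: it equals the fitted
parameter $C$ and is a property of the fit, not an observation; censoring it
would discard a reported quantity for 4-cm roots whose $C$ sits just past
the observable limit.

`stage_table()` cuts the profile into five stages — lag (apex to InP),
starting (InP to MAP), rapid (MAP to MDP), temperate (MDP to MVP$_{95}$),
plateau — with chord-slope mean rates. The rapid-stage rate has the closed
form $\approx 0.3167\,A B$ %/cm, independent of $C$ (`stage3_rate()`).

## The length-unified model

Fitting each root length separately and regressing the Ti-Gompertz
parameters on length $L$ reveals two regimes split at 13 cm: below it the
asymptote grows with length while the rate is constant; at and above it the
asymptote saturates while the rate grows. `fit_parameter_trends()` runs the
six simple regressions and freezes a parameter to its regime mean when the
slope's two-sided $p \ge 0.05$ — the threshold is inferred from which
relations are reported as constants versus lines, and is an argument. The
boundary length 13 cm belongs to the long regime. The published relations
(short: $A = 13.02 + 2.54L$, $B = 0.751$, $C = 3.20 - 0.047L$; long:
$A = 44.8$, $B = -0.748 + 0.119L$, $C = 4.43 - 0.139L$) ship as
`default_unified_coefficients()` and drive `predict_params()` /
`predict_AR()`. The two regimes do not meet continuously at exactly
$L = 13$; this is a property of the published piecewise fit and is
documented rather than patched.

## Volume

`aerenchyma_volume()` treats the root as a cylinder of its mean diameter
$d$ (mm) and integrates the percentage curve axially:
$V = \tfrac{\pi d^2}{4} \int_{x_0}^{x_1} \mathrm{AR}(x)/100\; dx$, converted
to mm$^3$. No closed form exists for the Gompertz integral, so adaptive
quadrature (absolute tolerance $10^{-8}$) is used, with a 10,000-panel
Simpson fallback. Bounds default to the whole root: the basal measurement
artifact is an assay property, not a hole in the root, so it is not excluded
from volume unless the caller asks.

## The synthetic generator

`generate_profile()` / `generate_dataset()` emulate the study design: root
lengths 2–16 cm, sections every 0.5 cm, 12 replicates per section, roots of
3 cm or less all-zero (aerenchyma starts in 4-cm roots), additive Gaussian
noise with sd 1% by default (residual spread in such assays is roughly
constant across the range; a constant-CV multiplicative option is provided),
values clamped to $[0, 100]$, and a 1% detection floor: sections whose
noiseless mean falls below it are scored 0, emulating what hand sectioning
can resolve. Everything is deterministic given the config seed.

What the generator does *not* emulate: the basal-segment dip (it is handled
by exclusion, not simulation), between-root biological variation at a given
length (one "true" curve per length), spatial correlation along a root, and
non-Gaussian measurement error. Tests passing on these synthetic data
therefore validate the estimation machinery under the stated noise model,
not the biology of any particular cultivar.

### Numerical and design notes

* The detection floor interacts with fitting: zeroed sub-threshold sections
  pull short-root fits off the generating parameters even without noise, so
  generator-vs-fitter consistency checks are run with the floor disabled,
  while the floor stays on for study-condition simulations.
* Short roots identify $A$ weakly: a 4-cm root is observed only to 3 cm,
  where the curve has reached barely a third of its asymptote, so the
  per-length estimates for 4–5-cm roots are intrinsically noisy and dominate
  the error in round-trip recovery of the length-unified coefficients. With
  12 replicates and 1% noise the recovered short-regime intercepts can be
  tens of percent off in any single realization; users fitting real short
  roots should lean on the bootstrap intervals rather than point estimates.
* Default problem sizes in the test-suite simulations (tens of seeds,
  hundreds to a thousand bootstrap replicates, 11–13 root lengths) were
  chosen as the smallest sizes at which the Monte-Carlo checks are stable.
* Exact surd constants $(3 \pm \sqrt5)/2$ are used for MAP/MDP rather than
  the rounded 2.618/0.382; the difference is below the reported precision.
* Ties in the model-competition ranking are broken BIC, then SSR, then the
  fixed family order — deterministic on noiseless data where all criteria
  coincide.

## Limitations

The package estimates a *descriptive* developmental curve; it does not model
root growth dynamics, cell death mechanisms, or treatment effects. The
unified coefficients are cultivar- and condition-specific: refit
`fit_parameter_trends()` on new material rather than reusing the defaults.
Volume assumes a cylindrical root of constant diameter, an adequate
approximation for adventitious rice roots but not for tapering root types.
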