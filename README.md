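# aerofit

Modelling the longitudinal pattern of aerenchyma formation in rice
adventitious roots.

Aerenchyma — gas-filled lacunae left by programmed death of root cortical
cells — lets rice roots pipe oxygen through flooded soil. On transverse
sections it is scored as the **aerenchyma percentage** (aerenchyma area /
cross-sectional area × 100), which rises sigmoidally with distance from the
root apex. `aerofit` is for root biologists and quantitative plant
scientists who section roots at regular intervals and want to turn those
profiles into interpretable developmental parameters.

The core model is the inflection-parameterized (Ti) Gompertz curve

    y(x) = A exp(−exp(−B (x − C)))

where `x` is distance from the apex (cm), `A` the asymptotic aerenchyma
percentage, `B` the rate (cm⁻¹) and `C` the inflection abscissa, at which
the curve always sits at `A/e` (36.8 % of the asymptote). The package

- fits four competing sigmoid families (W₀-Gompertz, Ti-Gompertz, logistic,
  von Bertalanffy) to per-position means by Levenberg–Marquardt least
  squares, and ranks them by R², SSR, AIC and BIC (`fit_profile()`,
  `compare_models()`);
- diagnoses parameter bias by residual bootstrap: percentile 95 % CIs, bias
  versus the OLS estimate and distribution skewness (`residual_bootstrap()`,
  `bias_report()`);
- extracts the critical points of the Ti-Gompertz curve — initial point,
  maximum acceleration point `C − ln((3+√5)/2)/B`, inflection point `C`,
  maximum deceleration point `C − ln((3−√5)/2)/B`, and the 95 %-of-maximum
  point — with censoring of points beyond the observable root, and the
  five-stage decomposition with per-stage formation rates
  (`critical_points()`, `stage_table()`);
- unifies the parameters as piecewise-linear functions of root length with
  a 13-cm breakpoint (`fit_parameter_trends()`, `predict_AR()`);
- integrates the fitted curve into whole-root aerenchyma volume, treating
  the root as a cylinder of its mean diameter (`aerenchyma_volume()`);
- generates synthetic datasets with the study's sampling design —
  0.5-cm sectioning, 12 replicates, 1 % detection floor, basal 1-cm
  exclusion — for fully reproducible testing (`generate_dataset()`);
- drives everything end to end from R (`run_pipeline()`) or the shell
  (`exec/aerofit`), reading and writing long-format CSV
  (`root_length_cm, position_cm, replicate_id, aerenchyma_pct`).

## Worked example

Simulate an 8-cm root under the study design, fit, and extract the biology:

```r
library(aerofit)

pr  <- generate_profile(8, generator_config(seed = 42))
fit <- fit_profile(pr, "ti_gompertz")
fit
#> ti_gompertz fit (converged)
#>       A       B       C
#> 32.8105  0.7840  2.8136
#> n = 15, SSR = 0.7386, R2 = 0.99967, AIC = -39.165, BIC = -37.041
```

The root would plateau at `A ≈ 32.8 %` aerenchyma; formation is fastest at
`C ≈ 2.81` cm from the apex. The Gompertz forms win the model competition
(identical curves, lowest AIC/BIC):

```r
compare_models(pr)
#>           family    A     B    C    R2   SSR    AIC     BIC converged rank
#>      ti_gompertz 32.8 0.784 2.81 1.000 0.739 -39.16 -37.041      TRUE    1
#>      w0_gompertz 32.8 0.784 9.08 1.000 0.739 -39.16 -37.041      TRUE    2
#>  von_bertalanffy 35.7 0.534 1.32 0.998 5.547  -8.92  -6.797      TRUE    3
#>         logistic 31.1 1.283 4.18 0.996 8.549  -2.43  -0.309      TRUE    4
```

Critical points (cm from the apex) and the five formation stages:

```r
cp <- critical_points(fit, root_length = 8)
cp
#> Ti-Gompertz critical points (cm from root apex):
#>   InP   MAP    IP   MDP MVP95
#> 1.219 1.586 2.814 4.041 6.602

stage_table(coef(fit), cp)
#>            stage    start      end      rate
#> 1        I (lag) 0.000000 1.219150 0.8171746
#> 2  II (starting) 1.219150 1.586088 3.7973777
#> 3    III (rapid) 1.586088 4.041135 8.1466431
#> 4 IV (temperate) 4.041135 6.601948 3.4271233
#> 5    V (plateau) 6.601948 7.000000 1.0842154
```

Aerenchyma detection starts 1.2 cm from the apex; the rapid stage runs from
1.6 to 4.0 cm, where the percentage climbs 8.1 points per cm. Bootstrap
diagnostics show the parameters are essentially unbiased with symmetric
sampling distributions:

```r
residual_bootstrap(fit, n_boot = 1000, seed = 42)
#> Residual bootstrap of a ti_gompertz fit: 1000 replicates (0 failed)
#>  parameter    ols boot_mean boot_sd ci_low ci_high ci_width      bias skewness
#>          A 32.811    32.815  0.1997 32.425  33.219   0.7940  4.21e-03   0.0470
#>          B  0.784     0.784  0.0141  0.756   0.814   0.0575 -1.55e-05   0.0525
#>          C  2.814     2.814  0.0145  2.786   2.841   0.0552  1.36e-04  -0.0645
```

Finally, the whole-root aerenchyma volume for a 1-mm-diameter root:

```r
aerenchyma_volume(8, mean_diameter = 1, params = fit)
#> Aerenchyma volume: 11.52 mm^3 (root 8.0 cm x 1.00 mm, integrated over [0.00, 8.00] cm)
```

The same pipeline runs from the shell:

```sh
Rscript exec/aerofit --simulate --seed 42 --out results/
Rscript exec/aerofit --input profiles.csv --out results/
```

writing `model_comparison.csv`, `bootstrap_summary.csv`,
`critical_points.csv`, `unified_coefficients.json`, `volumes.csv` and a run
log; identical inputs and seed give byte-identical outputs.

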