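# plssurv

Survival regression for datasets with many highly correlated covariates —
the situation in which neither the Cox model nor ordinary parametric
survival models can be fitted directly (multicollinearity, or p ≥ n).
`plssurv` composes two stages:

1. **Partial least squares (PLS)** extracts a small number C of orthogonal
   latent components from the standardized covariate matrix X, using log
   observed time as the working response (univariate NIPALS with deflation
   of X). The components are well defined for arbitrarily collinear
   designs and for p ≥ n.
2. **A flexible parametric (Royston–Parmar) survival model** uses the
   component scores as predictors. A restricted cubic spline s(ln t) models
   the baseline on a transformed survival scale:

   - *hazard* scale: ln H(t | z) = s(ln t) + β′z, with S = exp(−e^η);
   - *odds* scale: ln[(1−S)/S] = η, i.e. log cumulative odds of failure;
   - *normal* scale: −Φ⁻¹(S) = η (probit).

   With zero internal knots s(ln t) = η₀ + η₁ ln t and the three scales
   reduce exactly to the Weibull (ln H = ln λ + γ ln t + βz), log-logistic
   and lognormal models; each internal knot adds one curvature term while
   the spline stays linear beyond the boundary knots, which is what makes
   extrapolation of the cumulative hazard beyond the observed follow-up
   well defined.

Component coefficients are back-projected to per-covariate coefficients
via b = W(P′W)⁻¹β̂ (standardized scale), so every original covariate gets
an interpretable effect estimate.

The package also provides the **PLS-Cox** benchmark (a Cox proportional
hazards fit, Efron ties, on the identical component scores), a **Weibull
survival simulator** with block-autoregressive covariate correlation and
administrative censoring, 70:30 train/test splitting, and a comparison
harness that fits the six spline variants (3 scales × {0, 1} internal
knots) plus PLS-Cox on one shared split and decomposition and tabulates
AIC/BIC.

Full likelihoods are maximized by BFGS with analytic gradients; model
selection uses AIC = −2ℓ + 2k and BIC = −2ℓ + k ln n. The Cox row's
criteria use the partial likelihood — see the vignette for the caveat on
mixing likelihood types.

## Worked example

```r
library(plssurv)

spec <- simulation_spec(n = 100, p = 200, corr_max = 0.9, seed = 2026)
d <- simulate_dataset(spec)
d
#> Survival data: 100 subjects, 66 events, 200 covariates

cmp <- run_comparison(d, C = 2, train_fraction = 0.7, seed = 2026)
cmp
#> Model comparison (shared split and PLS decomposition, C = 2 )
#>  model_label  scale n_internal_knots C log_likelihood    aic    bic converged test_log_likelihood
#>    RP_plsH_0 hazard                0 2         -58.74 125.48 134.47      TRUE             -109.81
#>    RP_plsH_1 hazard                1 2         -57.20 124.40 135.64      TRUE             -109.73
#>    RP_plsO_0   odds                0 2         -59.09 126.18 135.17      TRUE              -95.20
#>    RP_plsO_1   odds                1 2         -57.14 124.28 135.53      TRUE              -99.47
#>    RP_plsN_0 normal                0 2         -58.55 125.10 134.10      TRUE             -159.48
#>    RP_plsN_1 normal                1 2         -56.47 122.95 134.19      TRUE             -184.21
#>      PLS-Cox   <NA>               NA 2        -113.52 231.05 235.55      TRUE              -87.44
#> Ranking by AIC: RP_plsN_1 > RP_plsO_1 > RP_plsH_1 > RP_plsN_0 > RP_plsH_0 > RP_plsO_0 > PLS-Cox
```

On this dataset the one-internal-knot spline variants rank highest, every
spline variant beats the PLS-Cox benchmark on AIC, and the direct
200-covariate fit would be refused (p ≥ n). Model labels read
`RP_pls<scale>_<knots>`: e.g. `RP_plsN_1` is the normal-scale spline model
with one internal knot. The baseline cumulative hazard of the best model,
including extrapolation past the 5-unit censoring horizon:

```r
best <- fit_pls_spline(split_train_test(d, 0.7, 2026)$train,
                       C = 2, scale = "normal", n_internal_knots = 1)
round(predict_cumulative_hazard(best$survival_stage, c(1, 2, 5, 8)), 4)
#> [1] 0.0003 0.1258 2.1446 4.6458
head(covariate_coefficients(best), 3)
#>   covariate coefficient
#> 1        x1  0.32887797
#> 2        x2  0.06436680
#> 3        x3 -0.01401096
```

The cumulative hazard is increasing in time, and the back-projected
coefficients are reported per covariate on the standardized scale (the
first 10 covariates carry the simulator's true effects).

A thin command-line front end over the same functions lives at
`inst/scripts/plssurv-cli.R` with `simulate`, `fit`, `compare` and
`predict` subcommands.

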