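---
title: "PLS-spline survival models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-spline survival models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plssurv)
```

## The problem

Epidemiological surveillance datasets routinely carry many covariates that
are strongly correlated with one another — survey instruments measuring
overlapping constructs, or simply more covariates than subjects. Both the
Cox model and ordinary parametric survival regressions assume away
multicollinearity and become unusable (or wildly unstable) in that regime.
`plssurv` addresses it by dimension reduction: partial least squares
compresses the covariates into a few orthogonal latent components, and a
flexible parametric survival model is fitted on the components.

## The survival stage

The flexible parametric (Royston–Parmar) model places a restricted cubic
spline in log time on a transformed survival scale. Writing
$\eta(t, z) = s(\ln t) + \beta' z$:

* **hazard** scale: $\ln H(t\mid z) = \eta$, so $S = \exp(-e^{\eta})$;
* **odds** scale: $\ln\{(1-S)/S\} = \eta$, so $S = 1/(1+e^{\eta})$;
* **normal** scale: $-\Phi^{-1}(S) = \eta$, so $S = \Phi(-\eta)$.

The spline is $s(x) = \eta_0 + \eta_1 x + \sum_j \eta_{j+1} v_j(x)$ with
one derived variable per internal knot $k_j$,
$$v_j(x) = (x-k_j)_+^3 - \lambda_j (x-k_{\min})_+^3
  - (1-\lambda_j)(x-k_{\max})_+^3, \qquad
  \lambda_j = \frac{k_{\max}-k_j}{k_{\max}-k_{\min}},$$
which is twice continuously differentiable and **exactly linear beyond the
boundary knots**. The linear tails are what licenses extrapolating the
cumulative hazard beyond the observed follow-up. With no internal knots
$s(\ln t) = \eta_0 + \eta_1 \ln t$, and the three scales collapse to the
Weibull ($\ln H = \ln\lambda + \gamma \ln t$, so
$\hat\lambda = e^{\hat\eta_0}$, $\hat\gamma = \hat\eta_1$), log-logistic,
and lognormal models. These closed-form reductions are the package's main
correctness anchors: the test suite checks log-likelihood agreement with
independent direct-parameterization censored MLEs (both hand-written
two-parameter optimizations and `survival::survreg`) to 1e-4 and better.

"Zero knots" and "one knot" always count *internal* knots. Boundary knots
sit at the extremes of the uncensored log event times; internal knots at
equally spaced centiles of the same values (one knot at the median — the
conventional default; the placement of a single internal knot is a genuine
free choice and median placement is adopted once and not revisited).
Censored times never influence knot placement.

### Likelihood, guard, optimization

Censored subjects contribute $\log S(t)$; events contribute
$\log f(t) = \log(-dS/d\eta) + \log(d\eta/d\ln t) - \ln t$. All
exponentials go through saturating, log-space formulations so that
$|\eta|$ up to 700 never yields a non-finite log-likelihood.

A fitted spline that is locally *decreasing* in log time at an event would
make $d\eta/d\ln t \le 0$ and the likelihood improper. The $\log$ of that
slope is therefore extended linearly below $\varepsilon = 10^{-8}$
(continuously differentiable, slope $1/\varepsilon$), which pushes the
optimizer firmly back toward proper fits; any event still sitting at a
nonpositive slope after convergence is counted in
`improper_hazard_events`. This guard is a numerical device, not a model
feature — it follows common practice in flexible-parametric
implementations.

Optimization is BFGS on the unconstrained coefficient vector with analytic
gradients on all three scales. Starting values are moment-style Weibull
estimates ($\gamma_0 = 1.28255/\mathrm{sd}(\ln t_{\text{events}})$, the
log-time standard deviation of a Weibull being $\pi/(\gamma\sqrt 6)$;
$\lambda_0$ the profile MLE given $\gamma_0$), with internal-knot and
regression coefficients started at zero; up to three deterministic
perturbed restarts precede a non-convergence flag. Standard errors from
the inverse observed information are available (`fit$vcov`) but are
secondary: no empirical variance claims are made beyond what the tests
compute.

Fits with $p \ge n$ raw predictors are *refused* with an explicit error:
the package's answer to that regime is the PLS stage, never a silently
ill-conditioned maximum-likelihood fit.

## The PLS stage

Components are extracted by univariate-response NIPALS: covariates are
standardized to training mean 0 / variance 1, the working response is
standardized log observed time, and each weight vector
$w_c \propto X_c' y$ is followed by deflation of $X$. Scores are mutually
orthogonal; held-out subjects are scored with the fixed training
projection $W(P'W)^{-1}$.

Three deliberate choices:

* **Censoring is ignored at the extraction stage.** The working response
  is log *observed* time, events and censored alike. This is the simplest
  reading of "components computed with time as the response", and it keeps
  the extraction identical for the spline and Cox stages so that model
  comparisons isolate the survival stage. A censoring-aware alternative
  (deflation against Cox residuals) exists and is noted as future work.
* **Default C = 2.** The component count is a tuning parameter with no
  canonical value; 2 is the smallest count that exercises multi-component
  behavior. It is overridable everywhere.
* **Sign convention**: each weight vector's largest-magnitude entry is
  made positive, so decompositions are bit-reproducible across platforms
  (PLS weights are otherwise determined only up to sign).

Component coefficients $\hat\beta$ back-project to covariate-level
coefficients $b = W(P'W)^{-1}\hat\beta$, reported on the standardized
covariate scale (an unstandardized report is available via
`covariate_coefficients(fit, unstandardized = TRUE)`). The identity
$T\hat\beta = X_s b$ is enforced by construction and tested to 1e-8.

The PLS-Cox benchmark fits a Cox model (Efron ties, via
`survival::coxph`) on the identical scores. Efron handling matters not for
the simulated continuous times but for ties introduced by round-tripping
data through delimited text.

## The simulator

`simulation_spec()` defaults encode the study conditions the comparison
harness is designed around: n = 100 subjects, p = 200 covariates,
Weibull event times with scale λ = 0.1 and shape γ = 1.5 under
proportional hazards, administrative censoring at 5 time units (under null
effects the censoring fraction is the analytic
$S(5) = e^{-0.1\cdot 5^{1.5}} \approx 0.327$), and pairwise covariate
correlations spanning 0 to 0.9.

The correlation structure is a design choice: covariates are split into up
to 10 contiguous blocks, block $b$ carrying first-order autoregressive
within-block correlation $\rho_b$, with the $\rho_b$ equally spaced over
$[0, 0.9]$ and zero correlation across blocks. AR(1) blocks realize the
full stated correlation range with a target matrix that is positive
definite for any $\rho < 1$, and the recursive construction samples it
exactly without a Cholesky step. Event times come from the inverse
transform $T = (-\ln U / (\lambda e^{x'\beta}))^{1/\gamma}$.

True effects default to a sparse vector — the first 10 covariates at 0.2,
the rest zero — chosen once as a realistic "a few moderate signals among
many correlated noise variables" configuration; parameter-recovery tests
use β = 0, where the marginal law is exactly Weibull. All generation is a
deterministic function of the spec's single seed (the time draws use a
fixed offset of the seed so they are independent of the covariate draws).

What the generator does *not* emulate: informative or covariate-dependent
censoring, non-proportional hazards, non-Gaussian covariates, and
competing risks. Passing tests therefore demonstrate correctness of the
machinery under a clean proportional-hazards Weibull world, not robustness
of the method on real surveillance data.

## The comparison harness

`run_comparison()` performs one 70:30 train/test split (70% training —
the conventional reading of a "70:30 split"), one PLS decomposition from
the training covariates, and seven fits on the shared training scores:
hazard/odds/normal × {0, 1} internal knots, plus PLS-Cox. AIC/BIC are
computed on the **training** fit; the held-out partition is additionally
scored with out-of-sample log-likelihood at the training coefficients.
Non-converged fits stay in the table, flagged, but are excluded from the
AIC ranking.

One methodological caveat is inherited deliberately: the Cox row's
criteria come from the *partial* likelihood while the spline rows use full
likelihoods. Comparing the two mixes likelihood types and systematically
disadvantages neither-in-a-calibrated-way; the harness reproduces this
comparison because it is the established benchmark protocol for this model
family, and the out-of-sample log-likelihood column is provided precisely
so that readers need not rest conclusions on the mixed-criteria ranking.
The spline stage's AIC/BIC count the intercept, spline terms and component
coefficients of the final model only; the PLS extraction is treated as a
fixed preprocessing step and not charged parameters — the comparison
treats components as given predictors, identically for every model, so the
ranking is unaffected.

## Problem sizes in the test suite

The suite anchors correctness at small-to-moderate sizes chosen for sharp
oracles rather than scale: n = 5 for the hand-expanded Cox partial
likelihood, n = 50–600 for oracle agreement (survreg, flexsurvspline,
mixOmics, OLS), n = 5000 × 20 replicates for Weibull parameter recovery
(mean shape within ±0.05, mean scale within ±0.01 of truth), 100 000
draws for marginal survival checks, and 20 replicates of the full n = 100,
p = 200 comparison for the directional claim that a spline variant beats
PLS-Cox on AIC in most datasets.

## Known limitations

* No time-varying effects, interval censoring, left truncation, frailty,
  stratification, or cure fractions.
* Knot counts are user-specified (0 or 1 in the comparison grid); there is
  no automated knot search, and no cross-validated choice of C.
* Uncertainty for back-projected covariate coefficients is not propagated
  through the PLS stage; the delta-method variances cover the survival
  stage only.
* The censoring-blind working response biases component directions when
  censoring is heavy and covariate-dependent.
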