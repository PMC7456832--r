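---
title: "Estimating mediated effects under mediator-outcome confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mediated effects under mediator-outcome confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdemed)
```

## The problem

In a randomized experiment with treatment $X \in \{0,1\}$, continuous
mediator $M$, and continuous outcome $Y$, the mediated (indirect) effect is
the part of the total treatment effect that travels through $M$. `cdemed`
works in the controlled-direct-effect (CDE) framework: assuming no
treatment–mediator interaction, the indirect effect is the total effect $c$
minus the CDE $c'$, and every estimator in the package reports it as
$\hat c - \hat c'$ with $\hat c$ the unadjusted least-squares slope of $Y$ on
$X$, shared across methods. Randomization identifies $c$; the difficulty is
$c'$, because the mediator is not randomized. Confounders of the $M$–$Y$
relation — possibly affected by the treatment (post-treatment confounders),
possibly unmeasured — make the naive adjustment for $M$ an adjustment for a
collider, opening spurious paths and biasing both $\hat c'$ and the mediated
effect.

## The generating model

The simulation framework draws data from the linear structural model

$$C_1 = gX + kU + e_3,\qquad C_2 = hX + nU + e_4,$$
$$M = aX + dC_1 + fC_2 + e_1,\qquad Y = c'X + bM + tU + e_2,$$

with $U, e_1,\dots,e_4 \sim N(0,1)$ independent and $k = n = t = 1$. $U$ is
never shown to the estimators; it induces the unmeasured part of the
$M$–$Y$ confounding through $C_1$ and $C_2$. When $g = h = 0$ the measured
confounders are baseline covariates; when $g, h \neq 0$ they are
post-treatment.

Path tracing gives the truths the Monte Carlo summaries are scored against:
$\mathrm{CDE} = c'$, indirect $= b(a + dg + fh)$ (reducing to the familiar
product $ab$ when $g = h = 0$), total $=$ their sum. The model description
we implement does not state this formula explicitly; it is the unique
linear-path-tracing value consistent with computing the indirect effect as
total minus direct, and with all structural paths at $0.59$ it evaluates to
$0.59(0.59 + 2 \cdot 0.59^2) = 0.7589$, matching the published true value
$0.759$.

Three generator details are our own conventions, since the design states the
distributions only as "normal" and the treatment only as "binary": treatment
allocation is balanced ($\Pr(X=1) = 0.5$, the natural reading of a
randomized two-arm experiment), all error variances are 1, and all
intercepts are 0. Intercepts and error scales shift or scale every fitted
model alike and do not alter any effect estimate's expectation, so nothing
downstream is sensitive to these choices.

## The five estimators

Let $\mathcal{C}$ denote the confounders a given specification includes.

**Regression with adjustment.** OLS of $Y$ on $X, M, \mathcal{C}$;
$\hat c'$ is the $X$ coefficient.

**IPW (and IPW-truncated).** For a continuous mediator, the propensity
weight is the stabilized normal-density ratio
$$w_i = \frac{\phi(M_i \mid X_i)}{\phi(M_i \mid X_i, \mathcal{C}_i)},$$
each density evaluated at the observed $M_i$ using the fitted value and
residual standard error of an OLS fit of $M$ (numerator: on $X$ only;
denominator: on $X$ and $\mathcal{C}$). The ratio form — confounder
prediction *relative to* treatment-only prediction — is what stabilizes the
weights; with no confounders the models coincide and $w \equiv 1$. The
outcome model $Y \sim M + X$ is then fitted by weighted least squares; no
confounder regressors appear, the weights carry the whole adjustment.
Because the treatment is randomized, only the outcome model is weighted (a
non-randomized treatment would also need a weighted $M$-on-$X$ model; that
extension is out of scope). The truncated variant winsorizes the weights at
the 1st/99th percentiles first. Binary mediators use the analogous
probability ratios $P(M{=}1|X)/P(M{=}1|X,\mathcal{C})$ (complement ratio for
$M=0$) from logistic fits.

**Sequential g-estimation.** Step 1 (Q-model): OLS of $Y$ on
$X, M, \mathcal{C}$ yields $\beta_M$. Step 2: the mediator's effect is
removed, and $Y - \beta_M M$ is regressed on $X$ alone; its slope $\psi$ is
the CDE. The step-2 regression may in general contain baseline covariates
but never post-treatment ones; since $X$ is randomized here, we include none
— one fewer modeling decision and no asymptotic difference.

**Doubly robust sequential g-estimation.** The Q-model is fitted by weighted
least squares with the IPW weights (built from the propensity confounder
set), then the unweighted residual-outcome regression proceeds as in
sequential g. If the Q-model is correctly specified, $\beta_M$ is consistent
regardless of the weights; if instead the propensity model is correct, the
weighting removes the confounding the Q-model misses — hence robustness to
single misspecification, and failure when both parts omit a confounder.
Whether the final residual-outcome regression should also be weighted is not
settled in the literature we follow; we default to unweighted (the weights'
job — making $M$ ignorable — is done inside the Q-model, and the final
stage's $X$ is randomized) and expose `weight_final_stage = TRUE` in
`doubly_robust_direct()` as the single switch isolating the other reading.

The misspecification batteries mirror the study design:
`two_confounder_battery()` gives all five methods both confounders;
`one_confounder_battery()` omits $C_2$ everywhere, except that the doubly
robust method contributes three variants ($C_2$ omitted from the propensity
model only, the Q-model only, or both), 7 specifications in all.

## Inference

`percentile_bootstrap()` draws whole-record resamples with replacement and
re-runs the *entire* pipeline on each — propensity fits, truncation caps,
Q-model, total effect — so the interval reflects nuisance-estimation
uncertainty, which is the reason bootstrapping is preferred over the naive
analytic standard error for $\psi$. Endpoints are symmetric nearest-rank
order statistics: ranks $k$ and $R + 1 - k$ with
$k = \lceil R(1-\alpha)/2 \rceil$, i.e. the 25th and 976th of $R = 1000$
resamples at the 95% level. A resample that loses a treatment arm is redrawn
(at most 100 attempts). Defaults: 1000 resamples, 95% level.

## Monte Carlo framework

`study_config()` + `run_study()` iterate conditions × replications ×
specifications. Per (condition, method): bias $= \bar{\hat\theta} - \theta$,
MSE $=$ mean squared deviation *from the truth*, relative bias
$= 100\,\mathrm{bias}/\theta$ (undefined at $\theta = 0$), and CI coverage
when the bootstrap is enabled. The source design describes MSE verbally as
variance plus squared bias but prints a formula measuring deviations from
the mean estimate (variance alone); we follow the verbal definition — MSE
about the truth, which exactly equals `var_estimate + bias^2`, both with
$1/R$ normalization — and emit `var_estimate` alongside `mse` so either
reading can be inspected. Replication seeds derive deterministically from
(master seed, condition index, replication index), so results are invariant
to execution order and parallel scheduling; a failed replication (e.g. a
degenerate weight model) is logged with its seed, counted in `n_failed`, and
excluded rather than aborting a long factorial run.

`zero_confounding_check()` is the built-in sanity condition
$d = f = g = h = 0$, under which every method — including plain regression —
must recover $ab$ within the 10% relative-bias acceptability bound.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sample_size` | 500 | records per simulated dataset |
| `replications` | 1000 | Monte Carlo replications per condition |
| `lower_pct`, `upper_pct` | 1, 99 | weight-truncation percentiles |
| `n_resamples`, `level` | 1000, 0.95 | bootstrap resamples and CI level |
| `k`, `n_coef`, `t` | 1 | unmeasured-confounder path strengths |

All structural coefficients are unitless linear-regression slopes on
standard-normal-error variables; 0.14, 0.39, 0.59 correspond approximately
to small, medium, and large effects.

## Numerical conventions and degenerate inputs

* Truncation caps use the nearest-rank percentile (the order statistic at
  rank $\lceil p \cdot n \rceil$) of the *current* weight vector, never
  pooled across replications or recycled across bootstrap resamples; the
  rule is exact on ties, bit-reproducible, and idempotent. The bootstrap
  interval uses the same nearest-rank convention, symmetrized.
* A denominator propensity model fitting $M$ perfectly (residual SD below
  $10^{-8}$ of the mediator's SD) is refused as degenerate rather than
  producing near-infinite density ratios; non-finite or non-positive weights
  are refused naming the offending records.
* Collinear regressors (coefficients dropped by `lm`) raise a
  degenerate-design error instead of silently reporting a reduced model.
* Single-arm datasets are rejected up front; single-arm bootstrap resamples
  are redrawn.
* `generate_dataset()` seeds its own RNG stream and restores the caller's,
  so interleaving generation with other simulation code cannot silently
  shift results.

## What the generator does and does not emulate

The synthetic data are exactly the linear–Gaussian world above: continuous
mediator and outcome, homoscedastic normal errors, no treatment–mediator
interaction, at most two measured confounders, one unmeasured confounder
acting through both. Passing tests therefore demonstrate correct behavior
*under this model* — they say nothing about skewed or binary mediators,
nonlinear confounding, interaction effects, or non-randomized treatments,
all of which are out of scope (the binary-mediator weight formulas are
provided for completeness but unexercised by the simulation study).

Two empirical notes from this model family are worth flagging. First, when
the confounder-to-mediator paths are large, the stabilized density ratio is
heavy-tailed (its population variance can be infinite even though its mean
is 1), which is precisely why IPW destabilizes there and why the mean-weight
≈ 1 diagnostic is only a reliable check at moderate confounding. Second, the
doubly robust estimator's single-misspecification protection is real in this
design: in our Monte Carlo runs the variants with only one misspecified part
stay near the 10% relative-bias bound while the both-misspecified variant
fails clearly — so blanket statements that *all* methods fail under omitted
confounding apply to the unprotected methods and the both-misspecified
variant, not to the singly misspecified doubly robust ones.

## Problem sizes used in the shipped checks

The packaged test suite and `scripts/acceptance.R` run the Monte Carlo
evaluations at 500 replications of $n = 500$ per condition (the full study
design uses 1000), bootstrap coverage at 200 replications × 500 resamples,
and the large-sample consistency oracles at $n = 10^5$. These sizes keep the
Monte Carlo standard errors a few times smaller than every margin being
tested while keeping a complete run on a single CPU in minutes.

## Known limitations

* Natural direct/indirect effects are defined in the literature but not
  estimated here; only the CDE-based difference $c - c'$ is.
* The CDE-based indirect effect equals the natural one only absent
  treatment–mediator interaction; no interaction models are fitted.
* No g-computation, propensity matching/stratification, sensitivity
  analysis, or non-linear outcome models.
* Relative bias is undefined for null true effects; summaries report `NA`
  there and comparisons must fall back on raw bias.
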