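---
title: "Modelling time-varying odds ratios in behaviour risk factor surveillance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time-varying odds ratios in behaviour risk factor surveillance data}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Behaviour risk factor surveillance (BRFS) systems draw a fresh random sample
of respondents every month, so the data are repeated independent
cross-sections: large, continuously growing, and with no longitudinal
linkage. The classic trend question ("is smoking declining?") can be
answered by aggregation, but the more interesting question — *is the
association between smoking and a sub-population changing?* — needs the
regression coefficients themselves to move over calendar time. trendvcm fits
logistic varying coefficient models (VCMs) for exactly this setting: the
Italian PASSI-style design with a binary outcome (current smoker), ten
categorical covariates, and a monthly wave index as the effect modifier.

## The model

For respondent $i$ in wave $t_i$, with covariates coded as treatment dummies
$Z_{ij}$ and level indicators $X_{ij}$,

$$\operatorname{logit} P(y_i = 1) \;=\; b_0 + \sum_j b_j Z_{ij} + a_0(t_i)
  + \sum_j X_{ij}\, a_j(t_i),$$

where the $b_j$ are constant coefficients and the $a_j(\cdot)$ are smooth
functions of time. Every varying covariate keeps its constant dummies; the
smooths — one per level, reference level included — describe departures from
the period-average effect.

Each smooth is a P-spline: a rich cubic B-spline basis (default `k = 55`
functions, one per observed month, equally spaced knots with degree-extended
boundaries) whose coefficients $\gamma_j$ are regularized by a second-order
difference penalty $\lambda_j \lVert \Delta_2 \gamma_j \rVert^2$. The basis
deliberately overfits; the penalty does the smoothing. The penalty's null
space is the linear functions, so as $\lambda_j \to \infty$ a varying
coefficient degenerates to a straight-line trend, and beyond that to the
constant already carried by the dummy.

Estimation minimizes the penalized deviance
$D(\beta) + \sum_j \lambda_j \lVert \Delta_2 \gamma_j\rVert^2$ by penalized
iteratively reweighted least squares (Fisher scoring) with step-halving, so
the objective is non-increasing across iterations; the Gaussian-identity
case reduces to the closed form
$\hat\gamma = (R^\top R + P)^{-1} R^\top y$ in one step. Note the factor-2
bookkeeping: penalizing the deviance ($-2\,\ell$) with $\lambda$ is the same
as penalizing the log-likelihood with $\lambda/2$; since $\lambda$ is chosen
from data the convention is immaterial, but it is the one under which the
Gaussian closed form above is exact.

### Identifiability

A constant coefficient and a free smooth for the same level are confounded,
so every smooth is centered: summed over the observed modifier values it is
constrained to zero, via an absorbed linear constraint that reduces each
block to $k-1$ columns. This makes the "constant OR" and "s(time)" rows of
the summary separately meaningful, and matches the generator's convention
that time-varying truths are mean-zero over waves. When *all* levels of a
varying covariate have smooths *and* a time-varying intercept is present,
the level smooths sum to a global smooth and an unpenalized linear direction
becomes exactly collinear; the solver detects the rank deficiency and
resolves it with a small proportional ridge (recorded in the fit). This is
inherent to the model family, not an artifact of the implementation.

## Smoothing-parameter selection

One $\lambda_j$ per smooth. The default criterion is GCV,
$n\,D / (n - \mathrm{edf})^2$, minimized over a 21-point common log-grid on
$[10^{-4}, 10^6]$ (each point a warm-started full fit) followed by
Nelder–Mead refinement of the per-term $\log\lambda_j$ (golden-section when
there is a single smooth). An approximate REML criterion (Laplace form:
penalized deviance plus $\log|X^\top W X + P| - \log_+|P|$) is available via
`method = "reml"`; it typically smooths slightly more than GCV. The search
is deterministic given the grid.

## Effective degrees of freedom and tests

Model complexity is measured by the trace of the influence matrix
$F = (X^\top WX + P)^{-1} X^\top WX$; unpenalized columns contribute exactly
1, so per-term values sum to the total. For *testing* we follow the
reference GAM software's residual-df convention and use
$\mathrm{tr}(2F - FF)$: the nested likelihood-ratio test takes
`statistic = deviance_null - deviance_alt` and
`df = edf2_alt - edf2_null`, with the p-value from the chi-square
distribution at fractional df (the regularized incomplete gamma function).

Two caveats, both quantified by this package's own simulations (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* The screening LRT is **anticonservative at moderate n**, because the
  deviance drop includes the adaptivity of smoothing-parameter selection.
  On all-constant surveys of about 5,000 respondents over 55 waves, the
  suite's 500-replicate calibration measures a size of roughly 0.12 at a
  nominal 0.05 (the acceptance script recomputes this rate at each run).
  The inflation is a property of this test family, not of the sample at
  hand, and shrinks as n grows, in line with the large-sample
  justification usually invoked for it; the surveillance analyses this
  package targets operate at n in the hundreds of thousands.
* Per-smooth Wald tests (reported by `summary()`) are approximate and tend
  to be optimistic; curves and bands should be read alongside them.

## Odds-ratio curves

For a non-reference level the overall effect is the constant estimate plus
the smooth departure; exponentiating gives the odds-ratio curve
$\mathrm{OR}(t) = \exp\{b_{\text{level}} + a_{\text{level}}(t)\}$.
Uncertainty comes from the Gaussian posterior of the coefficients with
covariance $(X^\top WX + P)^{-1}\phi$: bands are computed analytically for
the *combined* constant-plus-smooth effect (that is the quantity plotted and
interpreted), or by posterior simulation ($\ge$ 10,000 seeded draws) when
requested. Reference categories have no odds ratio by construction and are
refused. Exponentiation is monotone, so band ordering is preserved; at any
time point where the smooth departure crosses zero, the curve equals the
constant OR of the summary table.

## Model building

The two-stage procedure mirrors surveillance practice:

1. **Screening** (`screen_varying`): each covariate in turn (plus a
   time-varying intercept) is given smooths while all others stay constant,
   and tested against the all-constant logistic model by the nested LRT at
   $\alpha = 0.05$. Failures are recorded per row, never fatal.
2. **Forward selection** (`forward_select`): starting from the most
   significant screened term, the remaining screened-significant candidates
   are ranked by the share of the current model's *deviance-residual*
   variation explained by a Gaussian smooth fit ($1 - RSS/TSS$), and the
   best-ranked candidate is added when its LRT against the current model is
   significant. Smoothing parameters are re-selected at every candidate
   fit. After the variable candidates are exhausted the time-varying
   intercept is tested. Terms that failed screening are never added.
   A degenerate comparison (the larger model ending up with fewer effective
   df after re-smoothing) counts as evidence against the extra term.

Deviance residuals are used for the ranking because they are the standard
GLM residual; the original analysis did not state which residual its
deviance-explained step used. Significance takes precedence over AIC when
the two disagree, matching the selection rule of the analysis this package
operationalizes.

## The synthetic surveillance generator

Because PASSI microdata are not public, the generator is a first-class
module: independent monthly waves (default 55), covariates drawn
independently per respondent from declared marginals, and a Bernoulli
outcome whose log-odds combine constant log-ORs with mean-zero time-varying
departures (linear, sinusoid, piecewise, or sums of these). The `"passi"`
preset uses the published 2008–2012 marginal distributions (shipped as
`inst/extdata/passi_margins.csv`, 185,619 interviews) and the published
constant odds ratios (e.g. 2.08 for ages 18–29 versus 60–69, 0.47 for
non-drinkers versus high-risk drinkers); its time-varying truths decline for
the youngest age group (total log-OR change −0.211, the relative decline of
an OR moving from 2.1 to 1.7), more mildly for ages 40–49, and non-linearly
for non-drinkers. The intercept is calibrated by exact enumeration over the
covariate marginals so the period-average smoking prevalence is 27.9%.

What the generator does *not* emulate — and hence what passing tests cannot
speak to — are the design features of real surveillance data: stratified
sampling weights, cross-covariate dependence (an optional hook exists, but
no joint distribution is published to emulate), item nonresponse, and
clustering by local health unit.

### Problem sizes used in the checks

Verification scales are chosen to exercise the method at realistic
signal-to-noise: the full-scale recovery check uses 1,000 respondents per
wave over 55 waves (n = 55,000) with `k = 55`; screening calibration uses
about 5,000 respondents over 55 waves, 500 replicates; replicated
forward-selection recovery uses about 8,000 respondents per replicate with
effect amplitudes scaled up by roughly $\sqrt{n_{\text{full}}/n_{\text{test}}}$
so detectability matches the full-scale setting (at the published effect
sizes, time variation is only detectable near the full sample size —
Table-2-style screening statistics scale linearly with n). The expected
false-selection arithmetic is worth keeping in mind: with five candidates
screened at $\alpha = 0.05$, even a perfectly calibrated test leaves the
all-constant model intact in only $0.95^5 \approx 77\%$ of null datasets.

## Numerical choices

* PIRLS: relative penalized-deviance tolerance `1e-8`, max 100 iterations,
  binomial starting values $\mu = (y + 1/2)/2$, step-halving, first step
  accepted unconditionally (the heuristic start is not attainable by any
  coefficient vector).
* Deviance clamps fitted probabilities at `1e-16`; quasi-separation (over
  1% of $|\eta| > 23$) triggers a warning and a small ridge on the constant
  block.
* Non-positive-definite penalized systems get an escalating proportional
  ridge; non-PSD posterior covariances in the simulation band path are
  repaired by eigenvalue clipping, with a message.
* Missing data: listwise deletion with a reported count. No survey weights:
  the estimation target is the unweighted association structure, matching
  the analysis emulated.
* Ties in candidate ranking break alphabetically; the λ search is
  grid-then-refine and fully deterministic.

## Limitations

Smoothing-parameter uncertainty is ignored by the bands (pointwise coverage
in simulations sits near, and sometimes slightly below, nominal when the
truth is strongly curved); the screening LRT's size inflation at moderate n
is documented above; interactions, multiple effect modifiers, tensor-product
smooths and autocorrelated errors are out of scope — BRFS waves are
independent samples by design.
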