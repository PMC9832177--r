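---
title: "Testing dynamic mutualism in longitudinal symptom panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing dynamic mutualism in longitudinal symptom panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

A single general dimension of psychopathology — the *p*-factor — reliably
emerges when internalizing and externalizing symptom measures are factor
analysed together. Two developmental accounts compete to explain it. The
*common-cause* account treats *p* as a real latent vulnerability that drives
all symptom domains. *Dynamic mutualism* instead proposes that initially
weakly related symptom processes reinforce one another over development, so
that the positive manifold (and with it an apparent general factor) is an
emergent consequence of strengthening symptom-symptom interactions. A third
account, *differentiation*, predicts the opposite trajectory: symptom
domains decouple with age.

`pmutual` operationalizes the three-pronged statistical strategy for
distinguishing these accounts in annual panels of symptom-severity
composites (two internalizing measures — generalized anxiety and major
depression — and four externalizing measures — ADHD, conduct/antisocial
traits, oppositional defiance, and substance-use frequency):

1. **Longitudinal bifactor models.** Per wave, every composite loads on a
   general factor and on its domain factor (orthogonal within wave), with
   lag-1 autoregressions (and optionally all six cross-lagged paths) among
   the factors. If mutualistic strengthening is underway, the general
   factor's explained common variance (ECV), omega-hierarchical
   ($\omega_H$), and its standardized loadings should grow with age.
2. **Random-intercept cross-lagged panel models (RI-CLPM).** Stable
   between-person differences are absorbed by random intercepts; lag-1
   autoregressive and cross-lagged paths act on within-person deviations.
   Mutualism predicts that the bidirectional cross-lag model beats the
   baseline and unidirectional variants, with mostly positive cross-lags.
3. **Gaussian graphical models (networks).** Cross-sectional partial-
   correlation networks over the symptom nodes at three equidistant ages, at
   the between-person level (raw cross-sections) and the within-person level
   (person-mean-centered deviations), with centrality, small-worldness,
   bootstrap stability, and permutation comparison tests across ages.

An automated checklist aggregates the three prongs into the four study
hypotheses (H1–H4) and an overall verdict
(`consistent-with-mutualism` / `mixed` / `inconsistent`).

## The covariance-structure engine

All structural models compile to one engine (`sem_spec()` / `sem_fit()`)
with the implied moments

$$\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda' + \Theta,
\qquad \mu(\theta) = \nu + \Lambda (I-B)^{-1} \alpha,$$

estimated by maximizing the multivariate-normal log-likelihood (the ML,
$n$-denominator convention — stated explicitly because $\chi^2$ values shift
slightly between the $n$ and $n-1$ conventions). Missing data are handled
by full-information maximum likelihood: rows are grouped into missingness
patterns and pattern-wise Gaussian log-likelihoods are summed exactly (no
imputation). The saturated log-likelihood that anchors $\chi^2$, CFI, TLI
and RMSEA is closed-form on complete data and comes from an EM-estimated
unstructured Gaussian under missingness. Fit adequacy is labelled with the
conventional cutoffs CFI/TLI $\ge .90$ and RMSEA $\le .06$.

Numerical choices:

* Gradients are analytic (matrix identities on $d\Sigma/d\theta$), which is
  what makes panel-sized models (48 observed variables, ~200 parameters)
  fit in seconds.
* Optimizer: `nlminb` with variances box-bounded at 0; starting values are
  loadings at $0.5\,\mathrm{sd}$ of the indicator, residual variances at
  half the indicator variance, intercepts at the observed means. On
  non-convergence a deterministic high-communality fallback start is tried
  (residual variances near their boundary are a known hard region).
* Convergence is declared on the optimizer's own criterion, a scaled
  relative gradient below $10^{-5}$, or stationarity (a quasi-Newton
  restart no longer improves the objective by more than
  $10^{-6}(1+|F|)$). Well-specified models reach per-observation gradient
  components below $10^{-5}$; the invariant tests assert this.
* Standard errors come from the inverse observed information (central
  differences of the analytic gradient, step $10^{-5}\max(1,|\theta|)$).
* Robust (sandwich / scaled-$\chi^2$) corrections are deliberately **not**
  implemented: the synthetic panels this package validates against are
  multivariate normal, so normal-theory ML is exact for them. Analyses of
  heavy-tailed real data should bear this in mind.

**Identification of the bifactor models.** All latent variances (wave-1
variances and the residual variances of endogenous factors) are fixed to 1
with means 0, and loadings are free per wave — the standardized-factor
convention. A consequence is that *raw* loadings of later waves are not on
a common scale (the marginal factor variance accumulates through the
autoregression), so the endpoint "did the loading grow?" Wald test defaults
to completely standardized loadings via the delta method
(`endpoint_loading_wald(standardized = TRUE)`); the raw-label test remains
available. For the measurement-invariance ladder the scale moves where it
must: the metric model equates loadings across waves and frees the
endogenous factor variances; the scalar model equates intercepts and frees
the latent means — the standard longitudinal-invariance parameterization.

**Boundary tests.** Fixing random-intercept variances to zero puts the null
on the boundary of the parameter space, so the likelihood-ratio statistic
is chi-bar-square distributed. For a single boundary variance the exact
$(\tfrac12,\tfrac12)$ mixture of $\chi^2_0:\chi^2_1$ is used; for the CLPM
restriction (two variances plus their covariance) the customary
$\tfrac12(\chi^2_2+\chi^2_3)$ approximation is the default, and a
parametric-simulation method (seedable, default 500 draws) is available and
is validated against the known single-boundary weights in the test suite.

## Bifactor strength and reliability indices

From completely standardized loadings $\ell_g$ (general) and $\ell_s$
(specific, by domain) with residuals $\theta = 1 - \ell_g^2 - \ell_s^2$:

* $\mathrm{ECV}_g = \sum \ell_g^2 \big/ (\sum \ell_g^2 + \sum_s \sum \ell_s^2)$,
  and per-factor global ECVs that sum to one; the subscale-relative
  $\mathrm{ECV{\_}SS}$ is also reported because published tables are often
  on that scale (which of the two a given table shows is usually not
  derivable from its caption — both are emitted, labelled).
* $\omega = \big[(\sum\ell_g)^2 + \sum_s(\sum\ell_s)^2\big] / V_T$ and
  $\omega_H = (\sum\ell_g)^2 / V_T$ with the model-implied total-score
  variance $V_T = (\sum\ell_g)^2 + \sum_s(\sum\ell_s)^2 + \sum\theta$ (not
  the observed variance); subscale versions $\omega_S$, $\omega_{HS}$
  restrict every sum to one domain's indicators.
* Relative $\omega$ is $\omega_H/\omega$ (general) and
  $\omega_{HS}/\omega_S$ (specific) by definition.
* $H = \big[\sum \ell^2/(1-\ell^2)\big] \big/ \big[1 + \sum
  \ell^2/(1-\ell^2)\big]$; undefined (flagged) if any $|\ell| \ge 1$.

These formulas are checked to $10^{-10}$ against an independently written
arithmetic oracle on random admissible configurations.

## The synthetic-data generator

Because the motivating panel study's raw data are not publicly deposited,
the package ships a generator whose defaults emulate that design: ~2,300
subjects, 8 annual waves (ages 14–21), six composites (2 internalizing,
4 externalizing), moderate positive cross-domain correlations, wave-on-wave
autocorrelation, and monotone attrition with a 13% per-transition hazard
(≈87% per-wave retention; first wave always observed; an optional
missingness-at-random mode makes dropout depend on the previous wave's
severity through a logistic link).

Three data-generating processes:

* `common_cause`: latent $p$, INT and EXT follow independent stationary
  AR(1) chains (unit marginal variance; AR coefficients .75/.55/.60) and
  indicators load on $p$ and their domain factor. Default loadings are
  deliberately *heterogeneous* across measures ($\lambda_g$ =
  .50/.65/.65/.55/.60/.40, $\lambda_s$ = .55/.40/.30/.50/.40/.55): with
  near-proportional general and specific loading vectors the bifactor
  decomposition becomes empirically under-identified (two nearly collinear
  rank-one blocks), and loading recovery degrades sharply even at
  $n = 2000$ — heterogeneity is both more realistic and a conditioning
  requirement.
* `mutualism` / `differentiation`: no latent factors; the observed
  composites follow a lag-1 VAR whose cross-domain coefficients ramp
  linearly from `coupling_start` to `coupling_end` across transitions
  (0 → 0.3 for mutualism, 0.3 → 0 for differentiation; the total coupling
  is split evenly across source variables of the other domain, and the
  endpoint magnitude is of the order of the late-adolescence cross-lags
  reported for such panels). Innovations have unit variance and
  correlations .25 within domain and .10 across (independent innovations
  would leave almost no contemporaneous within-person association to
  analyse); wave 1 starts from a modest positive manifold (correlations
  .30 within, .15 across). Every transition matrix is checked for a
  spectral radius below 1 at configuration time. The coupling schedule is a
  calibration choice, not an estimate.

The generator always emits its ground truth (loadings or transition
matrices plus the complete pre-attrition panel) as an attribute, so every
downstream validation is a recovery test, and every run is fully seeded.

What the generator does *not* emulate: item-level ordinality (a Likert
discretizer exists but the pipeline's validation uses continuous
composites), non-normal heavy tails, informative attrition beyond the
single-variable logistic mechanism, cohort effects, and measurement
non-invariance (except when injected deliberately in tests). Passing
recovery tests on these panels therefore shows the machinery is correct
under its stated assumptions, not that those assumptions hold in any
particular real dataset.

## Networks

Unregularized GGMs are selected in two stages: candidate sparsity patterns
from thresholding the saturated partial-correlation matrix over a quantile
grid (default 100 levels), each refit by constrained maximum likelihood
(the classical modified-regression algorithm for covariance selection) and
scored by EBIC with $\gamma = 0.5$; then a greedy single-edge add/remove
search until the EBIC stops improving. On 4-node problems the selected
pattern matches exhaustive enumeration over all $2^6$ edge sets. Edge
weights are partial correlations of the final unpenalized fit.

Centrality uses edge lengths $1/|w|$: closeness is $(p-1)/\sum d$ over
reachable nodes (isolates get 0), betweenness counts shortest paths with
fractional credit for ties, expected influence is the signed row sum. The
small-worldness index binarizes the graph and compares transitivity and
mean path length with analytic random-graph expectations
($C_{rand}$ = density, $L_{rand} = \ln p / \ln \bar k$) — deterministic,
with no rewired-ensemble simulation; one of several SWI conventions in use.

Resampling: non-parametric subject bootstraps give 95% percentile CIs per
edge and bootstrap difference tests (significant when the CI of the
difference excludes zero); case-drop subsampling yields the
correlation-stability (CS) coefficient — the largest drop proportion at
which ≥95% of subsamples correlate at least .70 with the full-sample
centrality — labelled by the .70/.50/.25 tiers. A constant centrality
profile (e.g., an empty network) carries no rank information and counts as
not retained.

The permutation network comparison test reports $M$ (maximum absolute edge
difference) and $S$ (difference in global strength; sum of absolute edge
weights by default, signed sum by option), with per-edge Holm-adjusted
permutation tests when $M$ is significant. Re-running the full EBIC search
inside every permutation is computationally disproportionate for routine
use, so the permutation-loop estimator defaults to the saturated
partial-correlation network (the same estimator is used for the observed
and permuted statistics; the EBIC estimator can be requested). The paired
(within-subject) mode permutes dataset membership within subjects and
should be treated as experimental; unpaired is the default.

## The evidence checklist

The four hypotheses are evaluated by deterministic rules (all thresholds
configurable and logged):

* **H1**: at least half of the per-indicator endpoint Wald tests reject
  with positive direction, *and* ECV and $\omega_H$ of the general factor
  are higher at the last wave than the first. Indices and Wald tests come
  from the autoregressive bifactor fit — measurement-level quantities are
  markedly more stable there than in the cross-lagged fit, which instead
  serves the H3 comparison (and is warm-started from the autoregressive
  solution).
* **H2**: at least one significant positive within-person cross-lag in
  each direction in the bidirectional RI-CLPM.
* **H3**: the cross-lagged bifactor beats the autoregressive variant by
  LRT, *and* the bidirectional RI-CLPM has the lowest AIC in its family.
* **H4**: the cross-domain edge strength of the *between-person* networks
  increases from the first to the last compared age. Two design points
  deserve emphasis. First, the hypothesis is about strengthening
  internalizing–externalizing associations; the SWI is recorded per age
  (with its >1 and ≥3 classifications) but saturates toward 1 as a
  few-node network densifies, so an SWI-only rule is non-monotone in the
  very signal of interest — it remains available as `h4_rule = "swi"`.
  Second, the age trajectory is read at the between level because
  person-grand-mean centering mixes every wave into each deviation
  (deviation at the first age contains the negative mean of all later
  waves), contaminating within-level age contrasts; within-level networks
  are still estimated, reported and compared by NCT.

Verdict: `consistent-with-mutualism` if every evaluated hypothesis holds,
`inconsistent` if none does, otherwise `mixed`; hypotheses whose stage
failed are marked not-evaluated, and the verdict is withheld if nothing
could be evaluated.

## Problem sizes used in validation

The test suite validates at sizes chosen to make the statistical claims
sharp while remaining routine on a laptop: loading recovery on 20
synthetic panels of 2,000 subjects × 8 waves; test-size calibration over
200 null replicates at $n = 500$ (300 for the boundary test); RI-CLPM
selection over 50 replicates at $n = 700$; NCT size over 100 replicates ×
500 permutations at $n = 500$ per group and power over 30 replicates at
$n = 2000$; end-to-end discrimination over 20 seeds per generator at
$n = 1000$ with bootstraps disabled (the checklist does not consume
bootstrap output; a separate smoke test exercises the bootstrap path).
The acceptance script reruns the full pipeline on two fresh panels of
1,200 subjects × 8 waves.

## Known limitations

* Normal-theory ML only; no robust corrections, no categorical-indicator
  (WLSMV-style) estimation.
* The bifactor machinery is exercised with two specific factors; more are
  accepted by the configuration but untested.
* Lag-1 dynamics only, annual spacing assumed; no time-varying covariates.
* The within-person network decomposition is the person-grand-mean
  centering described above, with the caveats noted for age contrasts.
* The evidence checklist is one defensible operationalization of verbally
  stated hypotheses; its thresholds are configuration, not doctrine.
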