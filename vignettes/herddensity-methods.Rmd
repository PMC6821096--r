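---
title: "Modelling ungulate population density across a protection gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ungulate population density across a protection gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herddensity)
```

## The estimation problem

Ground-based line-transect surveys of ungulates produce, for each transect
segment and survey occasion, a set of detected herds with perpendicular
distances and herd sizes. Three processes separate those records from the
quantity of management interest, animals per km^2^:

1. **Imperfect detection** — the probability of seeing a herd declines with
   its perpendicular distance from the line.
2. **Availability** (temporary emigration) — a herd associated with a
   segment may be elsewhere, or unobservable, during a particular survey.
3. **Group structure** — density of *herds* must be scaled by expected
   *herd size*, and herd size responds to many of the same covariates that
   drive herd placement, so a single pooled mean size is biased.

`herddensity` composes three fitted models to cross that gap: a binned
(multinomial) distance-sampling model for herd density, a zero-truncated
Poisson (ZTP) regression for herd size, and bootstrap machinery that turns
the composition into stratified summaries and covariate-held-constant
contrasts across protection regions and years.

## Herd density: the hierarchical distance-sampling model

Detections are truncated at a species-specific distance $W$ and binned by
perpendicular distance with cutpoints $0 = c_0 < \dots < c_J = W$ (default
50 m bins; the bin width is a configuration choice, fine enough to shape
the detection function and coarse enough for stable cells). For segment
$i$, occasion $t$ and bin $j$ the count is modelled as

$$y_{itj} \sim \text{Poisson}\!\left(\lambda_i \, A_i \, \varphi_{it} \,
\pi_{ij}\right),$$

* $\lambda_i$ — herd density (herds/km^2^), log link, segment covariates;
  the strip area $A_i = 2 W L_i$ enters as a multiplicative offset so
  coefficients keep their density interpretation;
* $\varphi_{it}$ — availability, logit link, occasion-level covariates;
* $\pi_{ij} = \frac{1}{W}\int_{c_{j-1}}^{c_j} g(x)\,dx$ — bin detection
  probability under the uniform perpendicular-distance distribution of
  line-transect sampling, with $g$ a half-normal
  ($e^{-x^2/2\sigma^2}$), hazard-rate ($1 - e^{-(x/\sigma)^{-b}}$) or
  uniform key; $\log\sigma$ may carry segment covariates, the hazard shape
  $b$ is shared.

Because the synthetic super-population is redrawn independently each
occasion, the Poisson cell likelihood above is the exact likelihood for the
generated data, and estimated herd density is the product
$\hat D_i = \hat\lambda_i \bar{\hat\varphi}_i$.

**Identifiability.** With intercept-only availability, $\lambda$ and
$\varphi$ enter the cell means only through their product, and when
availability sits deep in the logistic tail the logit and log links become
indistinguishable — the likelihood has a nearly flat ridge and the two
intercepts can drift in opposite directions while their product stays
fixed. This is an inherent property of temporary-emigration distance
sampling, not of this implementation. The split is identified when
availability covaries with occasion and, crucially, when it approaches
saturation somewhere in the design (the logistic curvature near 1 cannot be
mimicked by rescaling $\lambda$). The synthetic truth therefore lets
availability rise toward saturation across the dry season
($\varphi = \mathrm{logit}^{-1}(1.0 + 1.5\,z_t)$, spanning roughly 0.2 to
0.96), which is also ecologically reasonable — herds concentrate near
surveyable water late in the dry season. Downstream summaries use the
product $\hat\lambda\bar{\hat\varphi}$, which is stable even where the
split is weak; `counterfactual_contrasts()` additionally drops (and
reports) coefficient draws that overflow the inverse links, a symptom of a
ridge-dominated fit.

**Numerics.** Half-normal bin integrals use the error-function closed
form; hazard-rate bins use 61-node Gauss–Legendre quadrature per bin
(agreement with adaptive quadrature is at machine precision on the scales
used here). The objective is minimized by `nlminb` with analytic gradients
for the $\lambda$ and $\varphi$ blocks and chain-rule gradients for the
detection block, followed by a damped Newton polish that drives the
gradient norm below $10^{-10}$ relative — this is what lets closed-form
identities (e.g. the uniform-key Poisson MLE) hold to $10^{-10}$ in tests.
Up to three jittered restarts are attempted on apparent non-convergence and
the convergence flag is always reported; standard errors come from the
inverse observed information. Continuous covariates are z-scored once when
the data object is built (the centring is frozen and re-applied to any new
data), quadratic terms use orthogonal polynomials through the model-frame
`predvars` mechanism, and the "log" functional form is `log1p` on the raw
scale because several covariates (percent cover, road distance) include 0.

**Goodness of fit** uses the Poisson deviance against the saturated model,
calibrated by a parametric bootstrap: data are simulated from the fitted
model, refitted, and the observed deviance is ranked among the simulated
ones. Counts this sparse make the asymptotic chi-square reference useless;
the bootstrap reference is the defensible one.

## Model selection

Fitting every combination of all covariates in one pool is infeasible, so
selection is staged, and the stages mirror how the covariates are typed:

1. **Detection**: all combinations of the detection covariates — the two
   vegetation-class descriptions are alternative codings of one variable
   and are never combined; the uniform key has no scale parameter and so
   takes no covariates — under hazard, half-normal and uniform keys, with
   intercept-only $\varphi$ and $\lambda$.
2. **Availability**: detection fixed at its AIC winner; all subsets of the
   availability pool.
3. **Super-population**: detection and availability fixed; five typed
   pools (abiotic, edge density, top-down, vegetation availability,
   anthropogenic) are searched separately — continuous covariates enter as
   linear, `log1p`, or orthogonal-quadratic terms — and the final set
   contains all additive combinations of the per-type winning blocks.

Ties at equal AIC go to the model with fewer parameters, then to the
lexicographically first formula; non-converged candidates are excluded and
listed. Predictions are model-averaged with Akaike weights
$w_m = e^{-\Delta_m/2}/\sum e^{-\Delta_m/2}$ over models within a
$\Delta$AIC window. The window defaults to 2.0: the selection rule quoted
with the study design says "within 1 AIC", yet its own reported averaged
sets include models up to $\Delta \approx 1.9$, so the wider window is the
behaviour consistent with the reported tables; it is configurable. When a
quantity depends on both $\lambda$ and $\varphi$, average the per-model
product rather than combining $\hat\lambda$ from one model with
$\hat\varphi$ from another — only the product is stably identified (the
`analysis/03` script does exactly this).

Before selection, `screen_covariates()` drops one member of each
continuous pair with $|r| > 0.6$ (the member explaining less marginal
variance in per-segment counts; deterministic and reported) and flags
categorical covariates with under-observed levels.

## Herd size: zero-truncated Poisson regression

Observed herds have at least one member, so sizes follow
$P(K = k) = e^{-\mu}\mu^k / \left(k!\,(1 - e^{-\mu})\right)$ with
$E[K] = \mu/(1 - e^{-\mu})$ and $\log\mu$ linear in covariates. The
likelihood is maximized with analytic gradients and the same Newton
polish; `log(-expm1(-mu))` keeps the normalizing term finite for tiny
$\mu$, which matters because the optimizer must be able to visit (and be
repelled from, not attracted to) the near-degenerate region. An all-ones
response puts $\hat\mu$ at the boundary and is flagged, not fitted.

Three procedural rules surround the regression:

* **Distance–size bias rule** — if a ZTP regression of size on distance
  shows evidence of association (default Wald $p < 0.15$; LR optionally),
  only herds on the line are used for size modelling, since large herds
  seen far out inflate naive size estimates. "On the line" defaults to
  recorded 0 m; for continuously simulated distances a small tolerance
  (10 m in the analysis scripts) stands in for the field recording
  convention. The threshold is deliberately liberal: missing a real bias
  costs more than dropping data.
* **Stepwise LR selection** — backward elimination at $\alpha = 0.05$ per
  test, then a forward pass over the dropped terms; a disagreement between
  passes is surfaced in the result rather than silently resolved.
* **Extrapolation guard** — expected sizes are only predicted for segments
  whose covariates lie inside the ranges observed among the fitted herds
  (unseen factor levels likewise); everything else is masked and counted.

The **Pearson-residual check** regresses $(y - \hat m)/\widehat{SD}$ on
$\hat m$ and reports intercept and slope with their p-values. Because the
ZTP score equations force the raw residuals to be orthogonal to the model
terms, this diagnostic is conservative: under a correct model it rejects
well below the nominal rate, and simulation shows its slope is essentially
insensitive to overdispersion. It is an informal adequacy check — useful
for catching gross mean-structure failures, not a calibrated test — and
with constant predictions (intercept-only models) the slope is undefined
and reported as `NA`.

## The predator-risk surface

Predation risk enters the density models as a covariate built from
relocation data: all animals' fixes are pooled with equal weight into one
bivariate-normal kernel utilization distribution on a 300 m grid, smoothed
by the 90th percentile of daily displacement distances (percentiles use
linear interpolation between order statistics, R type 7). The grid extent
is the bounding box of the fixes padded by $4h$, which keeps the grid
integral within $10^{-3}$ of 1; values are renormalized to integrate to
exactly 1. Segment midpoints sample the grid bilinearly, and the sampled
set is z-scored (SD with the $n-1$ convention) — raw values are returned
alongside because covariate summary tables conventionally report the raw
scale. Per-pride surfaces, temporal dynamics and GPS error are out of
scope.

## Population density, bootstrap, and counterfactual contrasts

Per segment, population density is the product
$\hat D_i \times \widehat{E[K]}_i$ (animals/km^2^); masked herd-size rows
propagate to masked densities and are excluded, with counts, from stratum
summaries. Regional (and optionally annual) means carry percentile
bootstrap intervals at 80/90/95%, resampling segments with replacement
within each stratum — the segment is the sampling unit that carries
covariates, so it is the exchangeable unit. With model-based per-segment
predictions the within-stratum spread reflects covariate variation only,
so intervals for sparsely parameterized species can be very narrow; that
is a faithful property of the plug-in surface, not an error.

Contrasts ask the counterfactual question: *how would density differ
across protection regions (or years) if every other covariate were held
fixed?* A prediction grid varies only region (through the `area` and
`side` covariates) and year, with continuous covariates at study-wide
means and categorical ones at reference levels ("mean value" is undefined
for a factor; the reference level is used and reported — an
observed-proportion blend would be an alternative). Uncertainty propagates
by drawing both models' coefficient vectors from their asymptotic
multivariate normal distributions and recomposing density per draw, which
matches model-based error bars better than segment resampling alone.
Year effects are additive on the log scale (no year-by-region
interaction), so annual fold-changes pool regions; regional fold-changes
average over years against the GMA baseline. Intervals are percentile at
80/90/95% and are nested by construction.

## What the synthetic generator does and does not emulate

`slpg_design()` reproduces the study geometry — 15 transects, 97 segments
(62/15/20 across west parklands, east parklands, GMA), segments at most
2 km, 10 occasions spanning four years and three dry-season stages with
the two logistically missed surveys. Continuous covariates are drawn from
their documented ranges with means matched via scaled Beta distributions
(concentration 4), which reproduces the skew of bounded covariates;
dynamic occasion covariates are categorical draws with configurable
(default uniform) probabilities. Herds arise Poisson per
segment-occasion, are thinned by availability, placed uniformly in
distance, detected by $g(x)$, and sized by a covariate-linked ZTP;
relocations follow a mean-reverting correlated random walk around activity
centres. Everything flows from one seed and equal seeds give identical
tables.

Real surveys differ in ways the generator deliberately ignores: spatial
autocorrelation between neighbouring segments, herd movement between
segments within a survey (double counting), observer heterogeneity,
rounded distances, and vegetation covariates derived from actual imagery.
Passing tests therefore demonstrate that the estimators recover the data-
generating process they assume — bias, coverage and calibration under the
model — not that the model is adequate for any particular field dataset;
the goodness-of-fit and residual diagnostics exist for that judgement.

## Validation problem sizes

The test suite validates the pipeline at the study scale: 600 replicate
surveys (97 segments x 10 occasions) for estimator bias and Wald coverage,
200 full pipeline replicates for fold-change contrast coverage (200
coefficient draws each), 2,000 replicates for the distance-bias rule's
null trigger rate, and 500 replicates for bootstrap interval coverage.
These sizes hold Monte-Carlo standard errors on coverage estimates near
0.01 while keeping the full suite under a few minutes on one CPU.

## Known limitations

* Continuous-distance (unbinned) likelihoods, negative-binomial
  super-populations, time-removal availability designs and spatially
  explicit models are out of scope; the Poisson mixture is the single
  supported super-population and the extension point is the cell-mean
  construction in the likelihood builder.
* The lambda/phi split is weakly identified whenever availability stays
  interior and occasion covariates are weak; report and interpret the
  product in that regime.
* The residual fit check is conservative (see above).
* Bootstrap intervals summarize plug-in prediction surfaces; they do not
  propagate distance-sampling estimation error into stratum means (the
  contrast machinery, which does propagate it, is the tool for formal
  comparisons).
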