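# herddensity

Estimating ungulate population density across a protection gradient from
repeated line-transect surveys — for ecologists and protected-area analysts
who need density estimates that correct for imperfect detection, temporary
emigration, and covariate-driven herd sizes, and who want to ask whether
protection status itself (rather than the ecology that correlates with it)
explains density differences.

## The models

**Herd density.** Detections within a truncation strip of half-width *W*
are binned by perpendicular distance. Bin counts follow a generalized
multinomial distance-sampling model with a Poisson herd super-population:

    y[i,t,j] ~ Poisson( lambda_i * A_i * phi_it * pi_ij )

with `lambda` herd density (herds/km², log link on segment covariates),
`A = 2WL` the strip area offset, `phi` per-occasion availability (logit
link), and `pi_ij` the integral of a half-normal, hazard-rate or uniform
detection function g(x) over bin *j* (uniform distance distribution, g(0)
= 1). Herd density is the product `D = lambda * phi`.

**Herd size.** Sizes (>= 1) follow a zero-truncated Poisson with log link,
mean `mu / (1 - exp(-mu))`; a distance–size regression (p < 0.15) decides
whether only on-line herds enter the size model, stepwise likelihood-ratio
tests select covariates, and predictions are masked outside the observed
covariate support.

**Selection and composition.** Detection, availability and five typed
super-population covariate pools are refined in three AIC stages;
predictions are Akaike-weight model averaged within a delta-AIC window.
Population density is `herd density x expected herd size` per segment,
summarized by stratified nonparametric bootstrap (80/90/95% percentile
CIs) and by counterfactual protection/year contrasts with all other
covariates held constant. A bivariate-normal kernel utilization
distribution built from predator relocations (bandwidth = 90th percentile
of daily displacements, 300 m grid) supplies the predation-risk covariate.

A seeded synthetic-survey generator (15 transects, 97 segments across
three protection regions, 10 dry-season occasions) provides known ground
truth for every stage, so the whole pipeline is testable end to end.

## Worked example

```r
library(herddensity)

design    <- slpg_design(seed = 1)                 # 97 segments, 3 regions
occasions <- generate_occasions(design, seed = 2)
truth     <- truth_params(formula_lambda = ~ area,
                          beta_lambda = c(log(2), 1),   # e-fold park effect
                          formula_size = ~ 1, beta_size = log(5))
detections <- simulate_survey(design, occasions, truth, seed = 3)

hd  <- hds_data(detections, design$segments, occasions, W = 300)
fit <- fit_hds(hd, formula_lambda = ~ area, formula_phi = ~ occ_z)
fit
#> Hierarchical distance-sampling fit (halfnorm key)
#>   logLik -2314.197  AIC 4638.393  params 5  herds 1025  converged: TRUE
#>                    estimate     se
#> lambda_(Intercept)   0.8240 0.1182
#> lambda_areapark      0.9247 0.1082
#> phi_(Intercept)      1.2977 0.4116
#> phi_occ_z            1.8757 0.3146
#> p_(Intercept)        4.5716 0.0239
```

The park coefficient (0.92 ± 0.11) recovers the simulated e-fold (1.0)
effect, and `exp(4.57) ≈ 97 m` recovers the 100 m detection scale. Compose
density and contrast regions:

```r
lam <- predict_hds(fit, type = "lambda")$estimate
phi <- mean(predict_hds(fit, type = "phi")$estimate)
zfit <- fit_ztp(herd_size ~ 1, detections)
cc <- counterfactual_contrasts(fit, zfit, n_draw = 1000, seed = 4)
cc$region_contrasts[, c("comparison", "fold", "lo95", "hi95")]
#>         comparison     fold    lo95     hi95
#> 1 park_east_vs_gma 2.521114 2.06946 3.149265
#> 2 park_west_vs_gma 2.521114 2.06946 3.149265
```

The estimated park:GMA density fold-change of 2.5 [2.1, 3.1] covers the
simulated truth (`exp(1) = 2.72`); the two parkland regions coincide here
because the fitted model carries no `side` effect.

## The analysis workflow

The `analysis/` scripts run the full study pipeline on the synthetic
system and write their tables under `results/`:

1. `01_simulate.R` — survey design, occasions, four species' detections,
   predator relocations (CSV + data dictionary).
2. `02_risk_surface.R` — displacement-percentile bandwidth, kernel UD
   (ESRI ASCII raster), standardized risk covariate per segment.
3. `03_herd_density.R` — truncation, three-stage AIC selection per
   species, deviance GOF, model-averaged herd densities.
4. `04_herd_size.R` — distance-bias rule, covariate screening, stepwise
   ZTP selection, residual check, guarded size predictions.
5. `05_population_density.R` — composition, stratified bootstrap CIs,
   protection/year contrasts.

`run_pipeline()` wraps the same stages as a single call for a named
species set.

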