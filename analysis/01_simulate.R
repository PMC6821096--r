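#!/usr/bin/env Rscript
# Step 1: simulate the study system.
#
# Builds the survey geometry (15 transects split into 97 segments across the
# protection gradient: 62 west-park, 15 east-park, 20 GMA), 10 dry-season
# survey occasions over four years, four ungulate species with known
# covariate-linked herd densities and herd sizes, and a set of lion
# relocations for the risk surface. Herds are recorded out to 400 m;
# species-specific truncation happens downstream. All tables land in
# results/data/.

suppressPackageStartupMessages(library(herddensity))

SEED <- 20120601
set.seed(SEED)

design <- slpg_design(seed = SEED, truncation_w_m = 400)
# planar segment midpoints (m) for sampling the risk surface
design$segments$x <- runif(97, 0, 20000)
design$segments$y <- runif(97, 0, 20000)
occasions <- generate_occasions(design, seed = SEED + 1)

truths <- list(
  impala = truth_params(formula_lambda = ~ area + side,
                        beta_lambda = c(log(2.5), 0.9, 0.4),
                        beta_phi = c(1.0, 1.5), sigma = 100,
                        formula_size = ~ area, beta_size = c(log(5), 0.3)),
  puku = truth_params(formula_lambda = ~ area + dist_river_km,
                      beta_lambda = c(log(1.5), 1.6, -0.15),
                      beta_phi = c(1.0, 1.5), sigma = 140,
                      formula_size = ~ 1, beta_size = log(5.5)),
  zebra = truth_params(formula_lambda = ~ area + side,
                       beta_lambda = c(log(0.6), 1.3, 0.5),
                       beta_phi = c(0.8, 1.2), sigma = 110,
                       formula_size = ~ 1, beta_size = log(5)),
  warthog = truth_params(formula_lambda = ~ area,
                         beta_lambda = c(log(0.5), 1.2),
                         beta_phi = c(0.8, 1.2), sigma = 90,
                         formula_size = ~ 1, beta_size = log(2.2))
)

detections <- do.call(rbind, lapply(names(truths), function(sp)
  simulate_survey(design, occasions, truths[[sp]], species = sp,
                  seed = SEED + match(sp, names(truths)))))

centers <- cbind(runif(6, 2000, 18000), runif(6, 2000, 18000))
locations <- simulate_relocations(6, 365, step_scale_m = 2500,
                                  centers = centers, seed = SEED + 9)

write_survey_tables("results/data", segments = design$segments,
                    detections = detections, occasions = occasions,
                    locations = locations)

cat("Simulated", nrow(detections), "herd detections across",
    length(truths), "species:\n")
print(table(detections$species))
cat("Tables written to results/data/\n")
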