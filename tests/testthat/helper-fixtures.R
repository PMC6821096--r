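# shared small fixtures, built in code

tiny_design <- function(seed = 1, n_occasions = 4) {
  generate_design(4L, c(3L, 3L, 2L, 2L), seed = seed,
                  region_by_transect = c("park_west", "park_west",
                                         "park_east", "gma"),
                  n_occasions = n_occasions)
}

# a full small survey with known truth; returns everything tests need
tiny_survey <- function(seed = 1, truth = truth_params(), n_occasions = 4) {
  design <- tiny_design(seed, n_occasions)
  occasions <- generate_occasions(design, seed = seed + 1)
  detections <- simulate_survey(design, occasions, truth, seed = seed + 2)
  list(design = design, occasions = occasions, detections = detections,
       truth = truth)
}

# big single-segment strip for distribution-level checks
strip_survey <- function(seed, truth, length_km = 200, W = 300,
                         n_occasions = 1) {
  design <- generate_design(1L, 1L, seed = seed, truncation_w_m = W,
                            region_by_transect = "park_west",
                            n_occasions = n_occasions)
  design$segments$length_km <- length_km
  occasions <- generate_occasions(design, seed = seed + 1)
  detections <- simulate_survey(design, occasions, truth, seed = seed + 2)
  list(design = design, occasions = occasions, detections = detections)
}
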