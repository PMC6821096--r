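test_that("study-scale design has 97 segments split across three regions", {
  d <- slpg_design(seed = 1)
  expect_equal(nrow(d$segments), 97L)
  expect_equal(as.vector(table(d$segments$region)[c("park_west", "park_east",
                                                    "gma")]),
               c(62L, 15L, 20L))
  expect_true(all(d$segments$length_km <= 2))
  # every covariate lies inside its documented range
  for (nm in names(herddensity:::.covariate_ranges)) {
    r <- herddensity:::.covariate_ranges[[nm]]
    expect_true(all(d$segments[[nm]] >= r[1] & d$segments[[nm]] <= r[2]),
                info = nm)
  }
})

test_that("designs are minimal-case safe, deterministic, and validated", {
  d1 <- generate_design(1L, 1L, seed = 1)
  expect_equal(nrow(d1$segments), 1L)
  expect_equal(length(d1$segments$edge_density), 1L)
  expect_identical(generate_design(3L, 2L, seed = 7),
                   generate_design(3L, 2L, seed = 7))
  expect_error(generate_design(0L, 1L), "positive")
  expect_error(generate_design(2L, c(1L, 0L)), "positive")
})

test_that("zero intensity produces an empty detection table", {
  s <- tiny_survey(seed = 3, truth = truth_params(beta_lambda = c(-40, 0)))
  expect_equal(nrow(s$detections), 0L)
  expect_true(all(c("segment_id", "distance_m", "herd_size") %in%
                    names(s$detections)))
})

test_that("detected-herd counts match the Poisson-thinning mean", {
  # uniform detection, phi = 1, constant lambda: detections ~ Poisson with
  # mean lambda * sum(area) * T (since sum pi = 1 for the uniform key)
  tr <- truth_params(formula_lambda = ~1, beta_lambda = log(3),
                     formula_phi = ~1, beta_phi = 20,  # plogis(20) ~ 1
                     key = "uniform")
  s <- strip_survey(seed = 11, truth = tr, length_km = 150, n_occasions = 4)
  area <- 2 * 0.3 * 150
  mean_n <- 3 * area * 4
  expect_lt(abs(nrow(s$detections) - mean_n), 3 * sqrt(mean_n))
})

test_that("detection distances follow the normalized detection function", {
  tr <- truth_params(formula_lambda = ~1, beta_lambda = log(60),
                     formula_phi = ~1, beta_phi = 20, sigma = 100)
  s <- strip_survey(seed = 13, truth = tr, length_km = 400, n_occasions = 2)
  expect_gt(nrow(s$detections), 1e4)
  br <- seq(0, 300, by = 50)
  obs <- table(cut(s$detections$distance_m, br))
  p <- drop(cell_probabilities("halfnorm", br, 300, sigma = 100))
  expect_gt(chisq.test(obs, p = p / sum(p))$p.value, 1e-3)
})

test_that("simulated herd sizes are >= 1 with the zero-truncated mean", {
  tr <- truth_params(formula_lambda = ~1, beta_lambda = log(4),
                     formula_phi = ~1, beta_phi = 20,
                     formula_size = ~1, beta_size = log(2.5))
  s <- strip_survey(seed = 17, truth = tr, length_km = 300)
  expect_true(all(s$detections$herd_size >= 1))
  m <- ztp_mean(2.5)
  se <- sd(s$detections$herd_size) / sqrt(nrow(s$detections))
  expect_lt(abs(mean(s$detections$herd_size) - m), 4 * se)
})

test_that("relocation walks collapse to their centres and are reproducible", {
  one <- simulate_relocations(1, 1, 500, centers = c(100, 200), seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(length(daily_displacements(one)), 0L)
  still <- simulate_relocations(2, 20, 1e-9, centers = rbind(c(0, 0), c(5, 5)),
                                seed = 2)
  expect_equal(max(abs(still$x[still$animal_id == 1])), 0, tolerance = 1e-6)
  expect_identical(simulate_relocations(3, 10, 100, c(0, 0), seed = 5),
                   simulate_relocations(3, 10, 100, c(0, 0), seed = 5))
  expect_error(simulate_relocations(0, 5, 1, c(0, 0)), "positive")
})

test_that("simulations with equal seeds are byte-identical", {
  a <- tiny_survey(seed = 21)
  b <- tiny_survey(seed = 21)
  expect_identical(a$detections, b$detections)
  expect_identical(a$occasions, b$occasions)
})
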