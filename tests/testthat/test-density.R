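test_that("species-specific truncation keeps the right rows and counts", {
  det <- data.frame(species = c("impala", "impala", "impala", "puku"),
                    distance_m = c(120, 299, 310, 390))
  tr <- truncate_detections(det, c(impala = 300, puku = 400))
  expect_equal(nrow(tr$detections), 3L)
  expect_equal(tr$counts$n_after[tr$counts$species == "impala"], 2L)
  # infinite W is the identity
  tr2 <- truncate_detections(det, c(impala = Inf, puku = Inf))
  expect_equal(tr2$detections, det)
  expect_error(truncate_detections(det, c(impala = 300)), "puku")
})

test_that("density composition multiplies aligned rows and propagates masks", {
  hd <- data.frame(segment_id = c("a", "b", "c"),
                   herd_density = c(2, 0, 1.5))
  sz <- data.frame(segment_id = c("a", "b", "c"),
                   mean_size = c(5, 7, NA))
  out <- compose_density(hd, sz)
  expect_equal(out$density, c(10, 0, NA))
  expect_error(compose_density(hd, sz[1:2, ]), "align")
})

test_that("stratified bootstrap gives degenerate CIs for constant data", {
  surface <- data.frame(segment_id = sprintf("s%d", 1:12),
                        region = rep(c("gma", "park_west"), each = 6),
                        density = rep(4.2, 12))
  bs <- bootstrap_strata(surface, strata = "region", n_boot = 50, seed = 1)
  expect_equal(bs$mean, c(4.2, 4.2))
  expect_equal(bs$lo95, bs$hi95)
  expect_equal(bs$hi95, c(4.2, 4.2))
  # same seed, same intervals; masked rows counted
  surface$density[1] <- NA
  b1 <- bootstrap_strata(surface, strata = "region", n_boot = 200, seed = 9)
  b2 <- bootstrap_strata(surface, strata = "region", n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  expect_equal(b1$n_masked, c(1L, 0L))
  expect_error(bootstrap_strata(surface, strata = "region", n_boot = 0),
               "at least 1")
  expect_error(bootstrap_strata(surface, strata = "nope"), "missing")
})

test_that("bootstrap mean converges to the plug-in stratum mean", {
  set.seed(61)
  surface <- data.frame(segment_id = sprintf("s%d", 1:30),
                        region = "gma", density = rlnorm(30))
  bs <- bootstrap_strata(surface, strata = "region", n_boot = 10000, seed = 2)
  mc_se <- sd(surface$density) / sqrt(30) / sqrt(10000) * sqrt(30)
  expect_lt(abs(bs$boot_mean - mean(surface$density)),
            3 * sd(surface$density) / sqrt(30 * 10000) * sqrt(30))
  expect_true(bs$lo80 >= bs$lo90)
  expect_true(bs$lo90 >= bs$lo95)
  expect_true(bs$hi80 <= bs$hi90 && bs$hi90 <= bs$hi95)
})

test_that("null protection effects give fold-changes straddling one", {
  tr <- truth_params(formula_lambda = ~ area, beta_lambda = c(log(3), 0),
                     formula_size = ~ 1, beta_size = log(4))
  s <- tiny_survey(seed = 62, truth = tr, n_occasions = 6)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~ area, fix_phi = 1)
  det_cov <- merge(s$detections, s$design$segments, by = "segment_id")
  zfit <- fit_ztp(herd_size ~ area, det_cov)
  cc <- counterfactual_contrasts(fit, zfit, n_draw = 400, seed = 63)
  pw <- cc$region_contrasts[cc$region_contrasts$comparison ==
                              "park_west_vs_gma", ]
  expect_lt(pw$lo95, 1)
  expect_gt(pw$hi95, 1)
  # interval nesting CI80 within CI90 within CI95
  expect_true(pw$lo95 <= pw$lo90 && pw$lo90 <= pw$lo80)
  expect_true(pw$hi80 <= pw$hi90 && pw$hi90 <= pw$hi95)
})

test_that("a known park effect on lambda is recovered by the contrasts", {
  tr <- truth_params(formula_lambda = ~ area, beta_lambda = c(log(2), 1),
                     formula_size = ~ 1, beta_size = log(4))
  s <- tiny_survey(seed = 64, truth = tr, n_occasions = 8)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~ area, fix_phi = 1)
  det_cov <- merge(s$detections, s$design$segments, by = "segment_id")
  zfit <- fit_ztp(herd_size ~ 1, det_cov)
  cc <- counterfactual_contrasts(fit, zfit, n_draw = 500, seed = 65)
  pw <- cc$region_contrasts[cc$region_contrasts$comparison ==
                              "park_west_vs_gma", ]
  expect_gt(pw$hi95, exp(1) * 0.98)
  expect_lt(pw$lo95, exp(1) * 1.02)
  # contrasts are reported against the season/yearly baseline too
  expect_true(all(grepl("_vs_", cc$year_contrasts$comparison)))
})

test_that("contrasts warn when protection appears in no model", {
  tr <- truth_params(formula_lambda = ~ 1, beta_lambda = log(3))
  s <- tiny_survey(seed = 66, truth = tr)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~ 1, fix_phi = 1)
  det_cov <- merge(s$detections, s$design$segments, by = "segment_id")
  zfit <- fit_ztp(herd_size ~ 1, det_cov)
  expect_warning(cc <- counterfactual_contrasts(fit, zfit, n_draw = 50,
                                                seed = 67),
                 "undefined")
  expect_equal(cc$region_contrasts$fold, c(1, 1))
})
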