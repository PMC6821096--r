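test_that("AIC and Akaike weights follow their definitions", {
  expect_equal(aic(-100, 5), 210)
  expect_equal(aic(0, 1), 2)
  expect_error(aic(0, 0), "at least 1")
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(sum(akaike_weights(c(3, 7, 2, 10))), 1)
  expect_equal(akaike_weights(c(3, 7, 2, 10)),
               akaike_weights(c(3, 7, 2, 10) + 55))
  # the weight pattern reported for closely competing models
  expect_equal(round(akaike_weights(c(0, 1.86)), 2), c(0.72, 0.28))
})

test_that("covariate screening drops collinear and imbalanced covariates", {
  set.seed(41)
  n <- 60
  x <- rnorm(n)
  z <- rnorm(n)
  # construct an exact target correlation via orthogonalized residuals
  make_cor <- function(x, z, r) {
    e <- residuals(lm(z ~ x))
    r * sd(e) * x / sd(x) + e * sqrt(1 - r^2)
  }
  seg <- data.frame(segment_id = sprintf("s%02d", 1:n), length_km = 1,
                    x = x,
                    dup = x,                      # r = 1
                    near = make_cor(x, z, 0.61),  # just over the threshold
                    ok = make_cor(x, rnorm(n), 0.59),
                    cat_bal = factor(rep(c("a", "b"), n / 2)),
                    cat_imb = factor(c(rep("a", n - 2), "b", "b")))
  det <- data.frame(segment_id = sample(seg$segment_id, 100, TRUE,
                                        prob = abs(x) + 0.1))
  sc <- screen_covariates(seg, det, covariates = c("x", "dup", "near", "ok",
                                                   "cat_bal", "cat_imb"))
  expect_true(sum(c("x", "dup") %in% sc$dropped) == 1)  # exactly one of a pair
  expect_true("near" %in% sc$dropped || "x" %in% sc$dropped)
  expect_true("ok" %in% sc$retained)
  expect_true("cat_imb" %in% sc$dropped)
  expect_true("cat_bal" %in% sc$retained)
  # idempotence: screening the retained set again changes nothing
  sc2 <- screen_covariates(seg, det, covariates = sc$retained)
  expect_equal(sort(sc2$retained), sort(sc$retained))
  expect_length(sc2$dropped, 0)
})

test_that("independent covariates are never dropped", {
  set.seed(42)
  seg <- data.frame(segment_id = sprintf("s%02d", 1:50), length_km = 1,
                    a = rnorm(50), b = rnorm(50), c = rnorm(50))
  det <- data.frame(segment_id = sample(seg$segment_id, 80, TRUE))
  sc <- screen_covariates(seg, det, covariates = c("a", "b", "c"))
  expect_length(sc$dropped, 0)
})

test_that("staged selection with empty pools yields a single final model", {
  s <- tiny_survey(seed = 43)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  pools <- list(detection = list(veg = character(0), other = character(0)),
                availability = character(0),
                lambda = list(anthropogenic = character(0)))
  sel <- staged_selection(hd, pools, keys = "halfnorm")
  expect_equal(nrow(sel$final$table), 1L)
  expect_equal(sel$final$table$model, "~1")
})

test_that("staged selection finds the active covariate and winner blocks", {
  tr <- truth_params(formula_lambda = ~ area, beta_lambda = c(log(2), 1.2))
  s <- tiny_survey(seed = 44, truth = tr)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  pools <- list(detection = list(veg = character(0), other = character(0)),
                availability = "stage",
                lambda = list(anthropogenic = "area", edge = "edge_density"))
  sel <- staged_selection(hd, pools, keys = c("halfnorm", "uniform"),
                          forms = "linear")
  expect_true(grepl("area", best_label(sel$final)))
  # the final pool contains every per-type winner alone, so the final best
  # AIC can never exceed any per-type winner's refit AIC
  for (nm in c("anthropogenic", "edge")) {
    expect_lte(sel$final$table$aic[1], sel[[nm]]$table$aic[1] + 1e-8)
  }
  # stage tables are sorted with weights summing to 1
  for (cs in sel) {
    expect_true(all(diff(cs$table$aic) >= 0))
    expect_equal(sum(cs$table$weight), 1)
  }
})

test_that("model averaging weights and averages predictions in the window", {
  s <- tiny_survey(seed = 45)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  f1 <- fit_hds(hd, ~1, ~1)
  cs1 <- herddensity:::candidate_set("final", "~1", list(f1))
  ma1 <- model_average(cs1)
  expect_equal(unname(ma1$weights), 1)
  expect_equal(ma1$estimate, predict_hds(f1, type = "lambda")$estimate)
  # two identical models tie at delta AIC 0 -> weights (0.5, 0.5)
  cs2 <- herddensity:::candidate_set("final", c("~1 ", "~1"), list(f1, f1))
  ma2 <- model_average(cs2)
  expect_equal(unname(ma2$weights), c(0.5, 0.5))
  # a model far outside the window is excluded
  f2 <- fit_hds(hd, ~ area + side + edge_density, ~1)
  big <- herddensity:::candidate_set("final", c("~1", "big"), list(f1, f2))
  if (diff(range(big$table$aic)) > 2)
    expect_length(model_average(big, window = 2)$weights,
                  sum(big$table$delta_aic <= 2))
})
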