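test_that("negative log-likelihood matches brute-force Poisson summation", {
  # one segment-occasion, one bin, expected mean 1, observed y = 1:
  # contribution is 1 - log(1) + log(1!) = 1
  seg <- data.frame(segment_id = "s1", length_km = 1 / 0.6, region = "gma")
  det <- data.frame(segment_id = "s1", occasion = 1, distance_m = 50)
  hd <- hds_data(det, seg, W = 300, cutpoints = c(0, 300), n_occasions = 1,
                 standardize = FALSE)
  # area = 2*0.3*(1/0.6) = 1 km^2; uniform key, phi = 1, lambda = 1 -> mean 1
  expect_equal(hds_negloglik(0, hd, key = "uniform", fix_phi = 1), 1)

  # all-zero counts: nll = sum of the means
  hd0 <- hds_data(det[0, ], seg, W = 300, cutpoints = c(0, 150, 300),
                  n_occasions = 2, standardize = FALSE)
  # mean per cell = exp(beta)*1*1*0.5; 2 occasions x 2 bins
  expect_equal(hds_negloglik(log(3), hd0, key = "uniform", fix_phi = 1),
               4 * 3 * 0.5)

  # random small instance: independent term-by-term oracle
  set.seed(42)
  segs <- data.frame(segment_id = c("a", "b", "c"),
                     length_km = c(1, 1.5, 0.8),
                     z = c(-0.3, 0.2, 1.1))
  dets <- data.frame(
    segment_id = sample(c("a", "b", "c"), 25, TRUE),
    occasion = sample(1:2, 25, TRUE),
    distance_m = runif(25, 0, 200))
  cp <- c(0, 100, 200)
  hd2 <- hds_data(dets, segs, W = 200, cutpoints = cp, n_occasions = 2,
                  standardize = FALSE)
  # oracle: explicit loops over segments, occasions, bins
  lam <- exp(0.4 + 0.8 * segs$z)
  area <- 2 * 0.2 * segs$length_km
  phi <- plogis(-0.2)
  sig <- 120
  oracle <- 0
  for (i in 1:3) for (t in 1:2) for (j in 1:2) {
    pij <- integrate(function(x) exp(-x^2 / (2 * sig^2)), cp[j], cp[j + 1],
                     rel.tol = 1e-12)$value / 200
    y <- sum(dets$segment_id == segs$segment_id[i] & dets$occasion == t &
               dets$distance_m > cp[j] & dets$distance_m <= cp[j + 1])
    m <- lam[i] * area[i] * phi * pij
    oracle <- oracle - (y * log(m) - m - lfactorial(y))
  }
  theta2 <- c(0.4, 0.8, -0.2, log(120))  # ~1 phi model has one coefficient
  got <- hds_negloglik(theta2, hd2, formula_lambda = ~z, formula_phi = ~1,
                       key = "halfnorm")
  expect_equal(got, oracle, tolerance = 1e-7)
})

test_that("uniform-key MLE equals the closed-form Poisson estimate", {
  tr <- truth_params(formula_lambda = ~1, beta_lambda = log(2),
                     formula_phi = ~1, beta_phi = 20, key = "uniform")
  s <- tiny_survey(seed = 5, truth = tr)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~1, key = "uniform", fix_phi = 1)
  lam_closed <- sum(hd$y) / (sum(hd$area_km2) * dim(hd$y)[2])
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$coef[1])), lam_closed, tolerance = 1e-10)
})

test_that("stacking a dataset twice doubles the log-likelihood only", {
  tr <- truth_params()
  s <- tiny_survey(seed = 6, truth = tr)
  hd1 <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  seg2 <- s$design$segments
  seg2$segment_id <- paste0(seg2$segment_id, "_b")
  det2 <- s$detections; det2$segment_id <- paste0(det2$segment_id, "_b")
  occ2 <- s$occasions; occ2$segment_id <- paste0(occ2$segment_id, "_b")
  hd2 <- hds_data(rbind(s$detections, det2),
                  rbind(s$design$segments, seg2),
                  rbind(s$occasions, occ2), W = 300)
  f1 <- fit_hds(hd1, ~area, fix_phi = 1)
  f2 <- fit_hds(hd2, ~area, fix_phi = 1)
  expect_equal(unname(f2$coef), unname(f1$coef), tolerance = 1e-6)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("predictions invert the links and reproduce fitted means", {
  tr <- truth_params(formula_lambda = ~1, beta_lambda = log(2))
  s <- tiny_survey(seed = 7, truth = tr)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~1, ~occ_z)
  p_lam <- predict_hds(fit, type = "lambda")
  expect_equal(p_lam$estimate, rep(exp(unname(fit$coef[1])), 10))
  p_phi <- predict_hds(fit, type = "phi")
  eta <- fit$coef["phi_(Intercept)"] + fit$coef["phi_occ_z"] *
    hd$occasions$occ_z
  expect_equal(p_phi$estimate, unname(plogis(eta)))
  # consistency with the likelihood's fitted means
  mu <- herddensity:::fitted_means(fit)
  pim <- cell_probabilities("halfnorm", hd$cutpoints, 300,
                            sigma = exp(unname(fit$coef["p_(Intercept)"])))
  recomputed <- p_lam$estimate[1] * hd$area_km2[3] *
    matrix(p_phi$estimate, 10, 4)[3, 2] * pim[1, 4]
  expect_equal(mu[3, 2, 4], recomputed, tolerance = 1e-12)
  # missing covariates in newdata are rejected
  expect_error(predict_hds(fit, data.frame(x = 1), type = "phi"), "missing")
})

test_that("aic slot matches -2 loglik + 2 k and SEs are positive", {
  s <- tiny_survey(seed = 8)
  hd <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  fit <- fit_hds(hd, ~area, ~occ_z)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_par)
  expect_true(all(fit$se[!is.na(fit$se)] > 0))
  expect_error(fit_hds(hds_data(s$detections[0, ], s$design$segments,
                                s$occasions, W = 300)),
               "no detections")
})

test_that("deviance GOF is zero at a saturated toy and flags gross misfit", {
  # data equal to fitted means: integer-valued toy via uniform key
  seg <- data.frame(segment_id = c("s1", "s2"), length_km = c(1, 1) / 0.6)
  det <- data.frame(segment_id = rep(c("s1", "s2"), each = 2),
                    occasion = 1, distance_m = c(50, 250, 50, 250))
  hd <- hds_data(det, seg, W = 300, cutpoints = c(0, 150, 300),
                 n_occasions = 1, standardize = FALSE)
  fit <- fit_hds(hd, ~1, key = "uniform", fix_phi = 1)
  # every cell holds exactly one herd and the fitted mean is exactly 1
  g <- deviance_gof(fit, n_boot = 5, seed = 1)
  expect_equal(g$deviance, 0, tolerance = 1e-8)
  expect_error(deviance_gof(fit, n_boot = 0), "at least 1")

  # a 10x misspecified intensity is rejected by the parametric bootstrap
  tr <- truth_params(formula_lambda = ~ area, beta_lambda = c(log(2), 2.3))
  s <- tiny_survey(seed = 9, truth = tr)
  hd2 <- hds_data(s$detections, s$design$segments, s$occasions, W = 300)
  bad <- fit_hds(hd2, ~1, ~occ_z)   # ignores a strong region effect
  g2 <- deviance_gof(bad, n_boot = 19, seed = 2)
  expect_lt(g2$p, 0.1)
})
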