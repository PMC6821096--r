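test_that("ZTP pmf closed forms, normalization and recurrence hold", {
  expect_equal(ztp_logpmf(1, 1), log(exp(-1) / (1 - exp(-1))))
  for (mu in c(0.2, 1, 5, 20)) {
    expect_equal(sum(exp(ztp_logpmf(1:200, mu))), 1, tolerance = 1e-9)
    k <- 1:10
    expect_equal(exp(ztp_logpmf(k + 1, mu) - ztp_logpmf(k, mu)),
                 mu / (k + 1), tolerance = 1e-12)
  }
  expect_error(ztp_logpmf(0, 1), "k must be integers >= 1")
  expect_error(ztp_logpmf(1, -1), "positive")
})

test_that("ZTP mean has the right limits and is increasing", {
  expect_equal(ztp_mean(1e-10), 1, tolerance = 1e-9)
  expect_equal(ztp_mean(1), 1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(ztp_mean(10), 10.00045, tolerance = 1e-5)
  mu <- seq(0.01, 12, length.out = 200)
  m <- ztp_mean(mu)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > pmax(1, mu)))
})

test_that("intercept-only MLE solves the mean equation", {
  set.seed(31)
  y <- herddensity:::rztpois(400, 3.2)
  fit <- fit_ztp(herd_size ~ 1, data.frame(herd_size = y))
  # independent oracle: 1-d root of ztp mean = sample mean
  root <- uniroot(function(m) m / (1 - exp(-m)) - mean(y),
                  c(1e-8, 50), tol = 1e-12)$root
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$coef[1])), root, tolerance = 1e-8)
  # fitted intercept-only mean equals the sample mean
  expect_equal(ztp_mean(exp(unname(fit$coef[1]))), mean(y), tolerance = 1e-8)
})

test_that("degenerate responses and null covariates are handled", {
  expect_warning(fit_ztp(herd_size ~ 1, data.frame(herd_size = rep(1L, 10))),
                 "boundary")
  set.seed(32)
  d <- data.frame(herd_size = herddensity:::rztpois(100, 2), zero = 0)
  f0 <- fit_ztp(herd_size ~ 1, d)
  f1 <- fit_ztp(herd_size ~ zero, d)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-8)
  expect_error(fit_ztp(herd_size ~ 1, data.frame(herd_size = c(0, 2))),
               ">= 1")
})

test_that("coefficient recovery is unbiased at moderate samples", {
  set.seed(33)
  est <- t(replicate(40, {
    x <- rnorm(300)
    mu <- exp(1 + 0.5 * x)
    d <- data.frame(herd_size = herddensity:::rztpois(300, mu), x = x)
    coef(fit_ztp(herd_size ~ x, d))
  }))
  expect_lt(abs(mean(est[, 1]) - 1), 0.05)
  expect_lt(abs(mean(est[, 2]) - 0.5), 0.05)
})

test_that("size-bias rule keeps all herds under the null, filters under bias", {
  set.seed(34)
  # strong simulated effect: sizes increase with distance -> filter fires
  n <- 250
  dist <- c(0, runif(n - 1, 0, 300))
  mu <- exp(0.5 + 0.008 * dist)
  det <- data.frame(distance_m = dist,
                    herd_size = herddensity:::rztpois(n, mu))
  res <- size_bias_test(det)
  expect_true(res$filtered)
  expect_true(all(res$detections$distance_m == 0))
  expect_lte(res$n_after, res$n_before)
  # no herds on the line at all is an error when the filter fires
  det2 <- det; det2$distance_m <- det2$distance_m + 1
  expect_error(size_bias_test(det2), "no herds on the line")
  # LR variant agrees qualitatively
  expect_true(size_bias_test(det, test = "lr")$filtered)
})

test_that("stepwise selection keeps strong terms and defaults to intercept", {
  set.seed(35)
  x <- rnorm(400); z1 <- rnorm(400); z2 <- rnorm(400)
  d <- data.frame(herd_size = herddensity:::rztpois(400, exp(1 + 0.6 * x)),
                  x = x, z1 = z1, z2 = z2)
  sel <- stepwise_select(d, c("x", "z1", "z2"))
  expect_true("x" %in% sel$kept)
  expect_length(sel$forward_conflicts, 0)
  sel0 <- stepwise_select(d, character(0))
  expect_equal(deparse(sel0$formula), "herd_size ~ 1")
})

test_that("Pearson-residual fit check is near zero for well-specified data", {
  # the ZTP score equations orthogonalize (y - m) against the model terms,
  # so for an adequate model the regression of Pearson residuals on fitted
  # sizes has intercept and slope near 0 and rejects at most at the nominal
  # rate (the diagnostic is conservative by construction)
  set.seed(36)
  rates <- replicate(30, {
    x <- rnorm(400)
    d <- data.frame(herd_size = herddensity:::rztpois(400, exp(1 + 0.4 * x)),
                    x = x)
    ck <- residual_fit_check(fit_ztp(herd_size ~ x, d))
    c(ck$intercept, ck$slope, ck$p_slope < 0.05, ck$p_intercept < 0.05)
  })
  expect_lt(abs(mean(rates[1, ])), 0.1)
  expect_lt(abs(mean(rates[2, ])), 0.05)
  expect_lte(mean(rates[3, ]), 0.05 + 0.07)   # at most ~nominal rejection
  expect_lte(mean(rates[4, ]), 0.05 + 0.07)
  expect_error(residual_fit_check(fit_ztp(herd_size ~ 1,
    data.frame(herd_size = c(2L, 3L)))), "at least 3")
  # intercept-only fit: constant predictions, slope undefined and flagged
  set.seed(37)
  f0 <- fit_ztp(herd_size ~ 1,
                data.frame(herd_size = herddensity:::rztpois(50, 3)))
  ck0 <- residual_fit_check(f0)
  expect_true(is.na(ck0$slope))
  expect_lt(abs(ck0$intercept), 0.5)
})

test_that("group-size prediction masks covariates outside observed ranges", {
  set.seed(37)
  d <- data.frame(herd_size = herddensity:::rztpois(200, 3),
                  x = runif(200, 0, 10))
  fit <- fit_ztp(herd_size ~ x, d)
  rng <- observed_ranges(d, "x")
  nd <- data.frame(x = c(5, max(d$x) * 1.01, min(d$x) - 0.1))
  pr <- predict_group_size(fit, nd, rng)
  expect_false(pr$masked[1])
  expect_true(all(pr$masked[2:3]))
  expect_true(all(is.na(pr$mean_size[2:3])))
  # a row identical to a fitted row reproduces its fitted mean
  nd2 <- d[7, , drop = FALSE]
  pr2 <- predict_group_size(fit, nd2, rng)
  mu7 <- exp(fit$coef[1] + fit$coef[2] * d$x[7])
  expect_equal(pr2$mean_size, unname(ztp_mean(mu7)))
  # intercept-only: all unmasked predictions identical
  f0 <- fit_ztp(herd_size ~ 1, d)
  pr0 <- predict_group_size(f0, nd, NULL)
  expect_equal(length(unique(pr0$mean_size)), 1L)
  expect_error(observed_ranges(d, "nope"), "unknown covariate")
})
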