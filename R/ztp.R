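# Zero-truncated Poisson regression for herd size.
#
# Herd sizes are counts >= 1; modelling them as Poisson conditioned on
# being positive gives P(K = k) = exp(-mu) mu^k / (k! (1 - exp(-mu))) with
# mean mu / (1 - exp(-mu)). The rate mu is log-linear in covariates.

#' Zero-truncated Poisson log-pmf
#'
#' @param k integer counts (>= 1).
#' @param mu positive Poisson rate(s).
#' @return log probabilities.
#' @examples
#' exp(ztp_logpmf(1, 1))  # e^-1 / (1 - e^-1)
#' @export
ztp_logpmf <- function(k, mu) {
  if (any(mu <= 0)) stop("`mu` must be positive")
  if (any(k < 1) || any(k != floor(k)))
    stop("zero-truncated support: k must be integers >= 1")
  # log(1 - exp(-mu)) via expm1 stays finite for tiny mu (log1p(-exp(-mu))
  # collapses to -Inf once exp(-mu) rounds to 1)
  stats::dpois(k, mu, log = TRUE) - log(-expm1(-mu))
}

#' Mean of the zero-truncated Poisson
#'
#' `mu / (1 - exp(-mu))`, the expected herd size given at least one animal.
#' Always exceeds `max(1, mu)` and tends to 1 as `mu -> 0`.
#'
#' @param mu positive rate(s).
#' @export
ztp_mean <- function(mu) {
  if (any(mu <= 0)) stop("`mu` must be positive")
  mu / (-expm1(-mu))
}

# variance of ZTP: m (1 + mu - m) with m = ztp_mean(mu)
ztp_var <- function(mu) {
  m <- ztp_mean(mu)
  m * (1 + mu - m)
}

#' Fit a zero-truncated Poisson regression
#'
#' Maximum likelihood with a log link on the rate mu, Newton-type
#' optimization with analytic gradients, and standard errors from the
#' observed information. An all-ones response puts the MLE at the `mu -> 0`
#' boundary and is flagged rather than reported as converged.
#'
#' @param formula model formula; the response are herd sizes (>= 1).
#' @param data data.frame with response and covariates.
#' @return object of class `ztp_fit` with `coef`, `se`, `vcov`, `loglik`,
#'   `aic`, `nobs`, `converged`, plus the model frame metadata needed by
#'   [predict_group_size()].
#' @export
fit_ztp <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 1) || any(y != floor(y)))
    stop("responses must be integer herd sizes >= 1")
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  if (all(y == 1)) {
    warning("all herd sizes are 1: ZTP rate MLE is at the mu -> 0 boundary")
    co <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
    return(structure(list(coef = co, se = co, vcov = NULL, loglik = 0,
                          aic = NA_real_, nobs = length(y), converged = FALSE,
                          boundary = TRUE, terms = trm,
                          xlev = stats::.getXlevels(trm, mf),
                          formula = formula, y = y, X = X),
                     class = "ztp_fit"))
  }
  nll <- function(beta) {
    mu <- exp(drop(X %*% beta))
    -sum(ztp_logpmf(y, mu))
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta))
    # d(-ll)/d eta = mu + mu e^-mu/(1-e^-mu) - y = ztp_mean adjustment
    -drop(crossprod(X, y - mu - mu * exp(-mu) / (-expm1(-mu))))
  }
  init <- numeric(ncol(X))
  init[1] <- log(max(mean(y), 1.01))
  opt <- stats::nlminb(init, nll, grad,
                       control = list(rel.tol = 1e-12, iter.max = 500))
  opt$par <- newton_polish(opt$par, nll, grad, tol = 1e-12)
  opt$objective <- nll(opt$par)
  gnorm <- max(abs(grad(opt$par)))
  converged <- gnorm < 1e-6 * max(1, abs(opt$objective))
  H <- stats::optimHess(opt$par, nll, grad)
  V <- try(solve(H), silent = TRUE)
  se <- rep(NA_real_, ncol(X))
  if (!inherits(V, "try-error") && all(diag(V) > 0)) se <- sqrt(diag(V))
  structure(list(
    coef = stats::setNames(opt$par, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = if (inherits(V, "try-error")) NULL else V,
    loglik = -opt$objective,
    aic = 2 * opt$objective + 2 * ncol(X),
    nobs = length(y), converged = converged, boundary = FALSE,
    terms = trm, xlev = stats::.getXlevels(trm, mf),
    formula = formula, y = y, X = X,
    data = data[rownames(mf), , drop = FALSE]
  ), class = "ztp_fit")
}

#' @export
logLik.ztp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
coef.ztp_fit <- function(object, ...) object$coef

#' @export
print.ztp_fit <- function(x, ...) {
  cat(sprintf("Zero-truncated Poisson fit: n = %d, logLik = %.3f, AIC = %.2f\n",
              x$nobs, x$loglik, x$aic))
  tab <- data.frame(estimate = x$coef, se = x$se,
                    change = exp(x$coef))
  print(round(tab, 4))
  invisible(x)
}

ztp_fitted_mu <- function(fit, newdata = NULL) {
  X <- if (is.null(newdata)) fit$X else {
    trm <- stats::delete.response(fit$terms)
    mf <- stats::model.frame(trm, newdata, xlev = fit$xlev)
    stats::model.matrix(trm, mf)
  }
  exp(drop(X %*% fit$coef))
}

#' Test and correct for herd-size detection bias with distance
#'
#' Large herds are easier to see far from the line, which biases naive mean
#' herd sizes upward. A ZTP regression of herd size on perpendicular
#' distance tests this; when the distance effect has p below `alpha`
#' (default 0.15), only herds recorded on the line (distance within
#' `on_line_tol` of 0) are retained for herd-size modelling, otherwise all
#' herds are kept.
#'
#' @param detections table with `herd_size` and `distance_m`.
#' @param alpha evidence threshold for the distance effect (default 0.15).
#' @param on_line_tol distances <= this count as "on the line" (default 0).
#' @param test `"wald"` (default) or `"lr"`.
#' @return list: `p_value`, `filtered` (logical: was the filter applied),
#'   `detections` (the retained rows), `n_before`, `n_after`.
#' @export
size_bias_test <- function(detections, alpha = 0.15, on_line_tol = 0,
                           test = c("wald", "lr")) {
  test <- match.arg(test)
  if (!all(c("herd_size", "distance_m") %in% names(detections)))
    stop("`detections` must carry `herd_size` and `distance_m`")
  f1 <- fit_ztp(herd_size ~ distance_m, detections)
  if (test == "wald") {
    z <- f1$coef["distance_m"] / f1$se["distance_m"]
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    f0 <- fit_ztp(herd_size ~ 1, detections)
    lr <- 2 * (f1$loglik - f0$loglik)
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  p <- unname(p)
  if (is.finite(p) && p < alpha) {
    keep <- detections$distance_m <= on_line_tol
    if (!any(keep))
      stop("size-bias filter leaves no herds on the line (distance <= ",
           on_line_tol, " m)")
    list(p_value = p, filtered = TRUE,
         detections = detections[keep, , drop = FALSE],
         n_before = nrow(detections), n_after = sum(keep))
  } else {
    list(p_value = p, filtered = FALSE, detections = detections,
         n_before = nrow(detections), n_after = nrow(detections))
  }
}

#' Stepwise likelihood-ratio selection of a herd-size model
#'
#' Backward elimination: repeatedly drops the candidate term whose
#' likelihood-ratio test against the current model has the largest p-value
#' above `alpha`, until all remaining terms test below `alpha`. A forward
#' pass over the dropped terms then confirms that none would re-enter at
#' `alpha`; any disagreement is reported in the result, not silently
#' resolved.
#'
#' @param data herd-size data (response `herd_size` plus covariates).
#' @param candidate_terms character vector of term labels.
#' @param alpha per-test LR threshold (default 0.05).
#' @return list: `formula`, `fit`, `kept`, `dropped`, `forward_conflicts`,
#'   `trace` (data.frame of steps).
#' @export
stepwise_select <- function(data, candidate_terms, alpha = 0.05) {
  build <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    stats::as.formula(paste("herd_size ~", rhs))
  }
  current <- candidate_terms
  trace <- list()
  fit_cur <- fit_ztp(build(current), data)
  repeat {
    if (!length(current)) break
    ps <- vapply(current, function(tm) {
      f0 <- fit_ztp(build(setdiff(current, tm)), data)
      lr <- 2 * (fit_cur$loglik - f0$loglik)
      stats::pchisq(max(lr, 0), df = length(fit_cur$coef) - length(f0$coef),
                    lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(ps)
    trace[[length(trace) + 1L]] <- data.frame(
      step = "backward", term = current[worst], p = ps[worst],
      action = if (ps[worst] >= alpha) "drop" else "stop")
    if (ps[worst] < alpha) break
    current <- setdiff(current, current[worst])
    fit_cur <- fit_ztp(build(current), data)
  }
  dropped <- setdiff(candidate_terms, current)
  conflicts <- character()
  for (tm in dropped) {
    f1 <- fit_ztp(build(c(current, tm)), data)
    lr <- 2 * (f1$loglik - fit_cur$loglik)
    p <- stats::pchisq(max(lr, 0), df = length(f1$coef) - length(fit_cur$coef),
                       lower.tail = FALSE)
    trace[[length(trace) + 1L]] <- data.frame(
      step = "forward", term = tm, p = p,
      action = if (p < alpha) "would_add" else "confirmed_out")
    if (p < alpha) conflicts <- c(conflicts, tm)
  }
  list(formula = build(current), fit = fit_cur, kept = current,
       dropped = dropped, forward_conflicts = conflicts,
       trace = do.call(rbind, trace))
}

#' Pearson-residual check of ZTP model fit
#'
#' Regresses Pearson residuals `(y - E[Y]) / SD[Y]` (ZTP mean and variance)
#' on predicted herd sizes; adequate fit corresponds to an intercept and a
#' slope not detectably different from 0.
#'
#' @param fit a converged `ztp_fit`.
#' @return list: `intercept`, `slope`, `p_intercept`, `p_slope`, `lm`.
#' @export
residual_fit_check <- function(fit) {
  if (!fit$converged) stop("residual_fit_check requires a converged fit")
  if (fit$nobs < 3) stop("need at least 3 observations")
  mu <- ztp_fitted_mu(fit)
  m <- ztp_mean(mu)
  r <- (fit$y - m) / sqrt(ztp_var(mu))
  if (stats::sd(m) == 0) {
    # constant predictions (intercept-only model): only the level is testable
    tt <- stats::t.test(r)
    return(list(intercept = mean(r), slope = NA_real_,
                p_intercept = tt$p.value, p_slope = NA_real_, lm = NULL))
  }
  lmfit <- stats::lm(r ~ m)
  sm <- summary(lmfit)$coefficients
  list(intercept = sm[1, 1], slope = sm[2, 1],
       p_intercept = sm[1, 4], p_slope = sm[2, 4], lm = lmfit)
}

#' Observed covariate ranges of the herds used in fitting
#'
#' @param data the herd observations used to fit the size model.
#' @param vars covariate names to document.
#' @return named list: numeric ranges for continuous covariates, observed
#'   level sets for factors.
#' @export
observed_ranges <- function(data, vars) {
  lapply(stats::setNames(vars, vars), function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    if (is.numeric(x)) range(x) else unique(as.character(x))
  })
}

#' Predict expected herd size with an extrapolation guard
#'
#' Expected herd sizes `ztp_mean(mu)` for new rows; any row whose
#' continuous covariates fall outside the ranges documented during herd
#' observations (or whose factor levels were never observed among herds) is
#' masked with `NA` and flagged instead of extrapolated.
#'
#' @param fit a `ztp_fit`.
#' @param newdata data.frame of covariates.
#' @param ranges result of [observed_ranges()] on the fitting herds; `NULL`
#'   disables the guard.
#' @return data.frame: `mean_size`, `masked`.
#' @export
predict_group_size <- function(fit, newdata, ranges = NULL) {
  masked <- rep(FALSE, nrow(newdata))
  if (!is.null(ranges)) {
    for (v in names(ranges)) {
      if (!v %in% names(newdata)) next
      x <- newdata[[v]]
      r <- ranges[[v]]
      if (is.numeric(r)) masked <- masked | x < r[1] | x > r[2]
      else masked <- masked | !(as.character(x) %in% r)
    }
  }
  mu <- ztp_fitted_mu(fit, newdata)
  out <- data.frame(mean_size = ztp_mean(mu), masked = masked)
  out$mean_size[masked] <- NA_real_
  out
}
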