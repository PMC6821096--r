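# Population density composition: herd density x herd size, stratified
# bootstrap summaries, and covariate-held-constant contrasts across the
# protection gradient and years.

#' Truncate detections at species-specific distances
#'
#' Keeps detections with perpendicular distance at most `W(species)` and
#' reports per-species sample sizes before and after truncation.
#'
#' @param detections detection table with `species` and `distance_m`.
#' @param w_by_species named vector of truncation distances (m), e.g.
#'   `c(impala = 300, puku = 400)`. `Inf` keeps everything.
#' @return list: `detections` (filtered), `counts` (data.frame with
#'   `species`, `W`, `n_before`, `n_after`).
#' @export
truncate_detections <- function(detections, w_by_species) {
  sp <- unique(detections$species)
  unknown <- setdiff(sp, names(w_by_species))
  if (length(unknown))
    stop("no truncation distance for species: ", paste(unknown, collapse = ", "))
  W <- w_by_species[detections$species]
  keep <- detections$distance_m <= W
  counts <- do.call(rbind, lapply(names(w_by_species), function(s) {
    sel <- detections$species == s
    data.frame(species = s, W = unname(w_by_species[s]),
               n_before = sum(sel), n_after = sum(sel & keep))
  }))
  list(detections = detections[keep, , drop = FALSE], counts = counts)
}

#' Compose herd density and herd size into population density
#'
#' Elementwise product of herd density (herds/km^2) and expected herd size
#' (individuals/herd) on aligned keys. Masked (NA) herd sizes propagate to
#' masked densities.
#'
#' @param herd_density data.frame with key columns and `herd_density`.
#' @param mean_size data.frame with the same key columns and `mean_size`.
#' @param by key columns, default `"segment_id"` (plus `"year"` if present
#'   in both).
#' @return data.frame with both inputs and `density = herd_density *
#'   mean_size` (animals/km^2).
#' @export
compose_density <- function(herd_density, mean_size, by = NULL) {
  if (is.null(by)) {
    by <- "segment_id"
    if ("year" %in% names(herd_density) && "year" %in% names(mean_size))
      by <- c(by, "year")
  }
  out <- merge(herd_density, mean_size, by = by, sort = FALSE)
  if (nrow(out) != nrow(herd_density))
    stop("keys of `herd_density` and `mean_size` do not align")
  out$density <- out$herd_density * out$mean_size
  out
}

#' Stratified nonparametric bootstrap of mean density
#'
#' Within each stratum the segment rows are resampled with replacement
#' `n_boot` times; percentile confidence intervals are reported at the 80,
#' 90 and 95% levels. Masked (NA) densities are excluded with their count
#' reported; an empty stratum is an error.
#'
#' @param surface data.frame with a `density` column and stratum columns.
#' @param strata character vector of stratum column names.
#' @param n_boot bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return data.frame: one row per stratum with `n`, `n_masked`, `mean`,
#'   and `lo80/hi80/lo90/hi90/lo95/hi95`.
#' @export
bootstrap_strata <- function(surface, strata = c("region", "year"),
                             n_boot = 1000, seed = NULL) {
  if (n_boot < 1) stop("`n_boot` must be at least 1")
  if (!all(strata %in% names(surface)))
    stop("stratum columns missing from `surface`")
  key <- interaction(surface[strata], drop = TRUE, lex.order = TRUE)
  groups <- split(surface, key)
  with_seed(seed, {
    rows <- lapply(names(groups), function(g) {
      d <- groups[[g]]
      v <- d$density
      n_masked <- sum(is.na(v))
      v <- v[!is.na(v)]
      if (!length(v)) stop("stratum ", g, " has no unmasked segments")
      boots <- vapply(seq_len(n_boot), function(b)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      qs <- stats::quantile(boots, c(0.10, 0.90, 0.05, 0.95, 0.025, 0.975),
                            names = FALSE)
      cbind(d[1, strata, drop = FALSE],
            data.frame(n = length(v), n_masked = n_masked, mean = mean(v),
                       boot_mean = mean(boots),
                       lo80 = qs[1], hi80 = qs[2], lo90 = qs[3],
                       hi90 = qs[4], lo95 = qs[5], hi95 = qs[6]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# one-row reference frame: numeric at the mean, factors at the reference
reference_row <- function(frame, skip = c("segment_id", "occasion")) {
  cols <- setdiff(names(frame), skip)
  out <- lapply(frame[cols], function(x) {
    if (is.numeric(x)) mean(x)
    else if (is.factor(x)) factor(levels(x)[1], levels = levels(x))
    else sort(unique(x))[1]
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

.region_map <- data.frame(
  region = factor(c("gma", "park_east", "park_west"),
                  levels = c("gma", "park_east", "park_west")),
  area = factor(c("gma", "park", "park"), levels = c("gma", "park")),
  side = factor(c("east", "east", "west"), levels = c("east", "west"))
)

#' Counterfactual density contrasts across protection and year
#'
#' Predicts herd density, availability and herd size on a grid that varies
#' only the protection region (through the `area` and `side` covariates)
#' and survey year, with every other continuous covariate fixed at its
#' study-wide mean and categorical covariates at their reference level.
#' Composed density draws are generated by sampling the fitted
#' coefficient vectors from their asymptotic multivariate-normal
#' distributions, giving fold-change contrasts of each region against the
#' baseline region (averaged over years) and of each year against the
#' baseline year (pooled over regions), with percentile intervals at the
#' 80, 90 and 95% levels.
#'
#' @param hds_fit a converged `hds_fit` whose data carry `area`, `side`
#'   and (for annual contrasts) `year`.
#' @param ztp_fit a converged `ztp_fit` for herd size.
#' @param n_draw coefficient draws (default 1000).
#' @param seed integer seed.
#' @param baseline_region,baseline_year baseline levels (defaults `"gma"`
#'   and the first year level).
#' @return list: `grid` (point predictions per region x year),
#'   `region_contrasts` and `year_contrasts` (fold-changes with CI80/90/95).
#' @export
counterfactual_contrasts <- function(hds_fit, ztp_fit, n_draw = 1000,
                                     seed = NULL, baseline_region = "gma",
                                     baseline_year = NULL) {
  stopifnot(inherits(hds_fit, "hds_fit"), inherits(ztp_fit, "ztp_fit"))
  if (!hds_fit$converged || !ztp_fit$converged)
    stop("contrasts require converged fits")
  seg_raw <- hds_fit$data$segments_raw
  occ_raw <- hds_fit$data$occasions_raw
  model_vars <- unique(c(all.vars(hds_fit$formulas$lambda),
                         all.vars(hds_fit$formulas$phi),
                         all.vars(stats::delete.response(ztp_fit$terms))))
  if (!any(c("area", "side") %in% model_vars))
    warning("neither `area` nor `side` appears in any model; ",
            "region contrasts are undefined (fold-change 1 by construction)")
  # lambda grid: one row per region
  lam_ref <- reference_row(seg_raw)
  regions <- .region_map$region
  lam_grid <- lam_ref[rep(1, length(regions)), , drop = FALSE]
  lam_grid$area <- .region_map$area
  lam_grid$side <- .region_map$side
  rownames(lam_grid) <- as.character(regions)
  # phi / size grid: one row per year (reference everything else)
  years <- if ("year" %in% names(occ_raw)) levels(occ_raw$year) else "all"
  occ_ref <- reference_row(occ_raw)
  phi_grid <- occ_ref[rep(1, length(years)), , drop = FALSE]
  if ("year" %in% names(occ_raw))
    phi_grid$year <- factor(years, levels = levels(occ_raw$year))
  baseline_year <- baseline_year %||% years[1]

  # design matrices (scaled internally via the fit's frozen scaling)
  Xl <- hds_design_matrix(hds_fit, lam_grid, "lambda")
  Xp <- if (is.null(hds_fit$model$phi)) NULL
        else hds_design_matrix(hds_fit, phi_grid, "phi")
  # ztp grid: region-major rows, year varying fastest
  zt_grid <- cbind(
    lam_grid[rep(seq_along(regions), each = length(years)), , drop = FALSE],
    phi_grid[rep(seq_along(years), length(regions)),
             setdiff(names(phi_grid), names(lam_grid)), drop = FALSE])
  zt_grid$.region <- rep(as.character(regions), each = length(years))
  zt_grid$.year <- rep(years, length(regions))
  trm_z <- stats::delete.response(ztp_fit$terms)
  mf_z <- stats::model.frame(trm_z, zt_grid, xlev = ztp_fit$xlev)
  Xz <- stats::model.matrix(trm_z, mf_z)

  dens_for <- function(beta_h, beta_z) {
    lam <- exp(drop(Xl %*% beta_h[hds_fit$model$idx$lambda]))
    phi <- if (is.null(Xp)) rep(hds_fit$fix_phi, length(years))
           else stats::plogis(drop(Xp %*% beta_h[hds_fit$model$idx$phi]))
    msize <- ztp_mean(exp(drop(Xz %*% beta_z)))
    # region x year matrices; Xz rows run year-within-region
    lam_m <- matrix(lam, length(regions), length(years))
    phi_m <- matrix(phi, length(regions), length(years), byrow = TRUE)
    sz_m <- t(matrix(msize, nrow = length(years)))
    lam_m * phi_m * sz_m
  }
  point <- dens_for(hds_fit$coef, ztp_fit$coef)
  dimnames(point) <- list(as.character(regions), years)

  Vh <- hds_fit$vcov
  if (anyNA(Vh)) stop("hds fit has no valid covariance matrix")
  draws_h <- with_seed(seed, MASS::mvrnorm(n_draw, hds_fit$coef, Vh))
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  draws_z <- with_seed(seed2, MASS::mvrnorm(n_draw, ztp_fit$coef, ztp_fit$vcov))
  dens_arr <- array(NA_real_, c(length(regions), length(years), n_draw))
  for (d in seq_len(n_draw))
    dens_arr[, , d] <- dens_for(draws_h[d, ], draws_z[d, ])

  ci_cols <- function(x) {
    # draws that overflow the inverse links signal a poorly identified fit;
    # they are excluded from the percentile intervals with a warning
    if (any(!is.finite(x))) {
      warning(sprintf("%d of %d contrast draws were non-finite and dropped",
                      sum(!is.finite(x)), length(x)))
      x <- x[is.finite(x)]
    }
    if (!length(x)) stop("no finite contrast draws")
    qs <- stats::quantile(x, c(0.10, 0.90, 0.05, 0.95, 0.025, 0.975),
                          names = FALSE)
    data.frame(lo80 = qs[1], hi80 = qs[2], lo90 = qs[3], hi90 = qs[4],
               lo95 = qs[5], hi95 = qs[6])
  }
  ib <- match(baseline_region, as.character(regions))
  region_contrasts <- do.call(rbind, lapply(
    setdiff(seq_along(regions), ib), function(i) {
      folds <- apply(dens_arr, 3, function(m) mean(m[i, ]) / mean(m[ib, ]))
      cbind(data.frame(comparison = sprintf("%s_vs_%s", regions[i],
                                            baseline_region),
                       fold = mean(point[i, ]) / mean(point[ib, ])),
            ci_cols(folds))
    }))
  jb <- match(baseline_year, years)
  year_contrasts <- do.call(rbind, lapply(
    setdiff(seq_along(years), jb), function(j) {
      folds <- apply(dens_arr, 3, function(m) mean(m[, j]) / mean(m[, jb]))
      cbind(data.frame(comparison = sprintf("%s_vs_%s", years[j],
                                            baseline_year),
                       fold = mean(point[, j]) / mean(point[, jb])),
            ci_cols(folds))
    }))
  list(grid = point, region_contrasts = region_contrasts,
       year_contrasts = year_contrasts,
       baseline = c(region = baseline_region, year = baseline_year))
}

# design matrix for predict-type computations on new raw-scale data
hds_design_matrix <- function(fit, newdata, type = c("lambda", "phi")) {
  type <- match.arg(type)
  blk <- if (type == "lambda") fit$model$lam else fit$model$phi
  nd <- apply_scaling(newdata, fit$data$scaling)
  trm <- stats::delete.response(blk$terms)
  mf <- stats::model.frame(trm, nd, xlev = blk$xlev)
  stats::model.matrix(trm, mf)
}
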