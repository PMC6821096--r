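# Table readers/writers and the end-to-end pipeline driver.
# All tables are CSV (header row, UTF-8, "." decimal); the data dictionary
# written next to them documents every column.

.segment_required <- c("segment_id", "length_km", "region")
.detection_required <- c("species", "segment_id", "occasion", "distance_m",
                         "herd_size")

#' Read and validate survey tables
#'
#' Reads the segment and detection tables (and optionally the occasion
#' covariate table), checking required columns, region levels, segment
#' references and distances. Errors name the offending rows.
#'
#' @param segment_path,detection_path,occasion_path CSV paths.
#' @return list: `segments`, `detections`, `occasions` (NULL if not given).
#' @export
read_survey_tables <- function(segment_path, detection_path,
                               occasion_path = NULL) {
  segments <- utils::read.csv(segment_path, stringsAsFactors = FALSE)
  detections <- utils::read.csv(detection_path, stringsAsFactors = FALSE)
  miss <- setdiff(.segment_required, names(segments))
  if (length(miss))
    stop("segment table is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(.detection_required, names(detections))
  if (length(miss))
    stop("detection table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!segments$region %in% .region_levels)
  if (length(bad))
    stop("unknown region labels in segment rows: ", paste(bad, collapse = ", "))
  segments$region <- factor(segments$region, levels = .region_levels)
  for (v in c("side", "area", "veg_class", "veg_class_simple", "path_type"))
    if (v %in% names(segments)) segments[[v]] <- factor(segments[[v]])
  bad <- which(detections$distance_m < 0)
  if (length(bad))
    stop("negative distances in detection rows: ", paste(bad, collapse = ", "))
  bad <- which(!detections$segment_id %in% segments$segment_id)
  if (length(bad))
    stop("detections reference unknown segments at rows: ",
         paste(bad, collapse = ", "))
  occasions <- NULL
  if (!is.null(occasion_path)) {
    occasions <- utils::read.csv(occasion_path, stringsAsFactors = FALSE)
    for (v in c("year", "stage", "grass_height", "grass_color", "water",
                "burn", "lagoon"))
      if (v %in% names(occasions)) occasions[[v]] <- factor(occasions[[v]])
  }
  list(segments = segments, detections = detections, occasions = occasions)
}

#' Write survey tables with a data dictionary
#'
#' @param dir output directory (created if needed).
#' @param segments,detections,occasions,locations tables to write; any may
#'   be `NULL`.
#' @return invisibly, the paths written.
#' @export
write_survey_tables <- function(dir, segments = NULL, detections = NULL,
                                occasions = NULL, locations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  if (!is.null(segments)) paths <- c(paths, wr(segments, "segments"))
  if (!is.null(detections)) paths <- c(paths, wr(detections, "detections"))
  if (!is.null(occasions)) paths <- c(paths, wr(occasions, "occasions"))
  if (!is.null(locations)) paths <- c(paths, wr(locations, "locations"))
  dict <- c(
    "Data dictionary",
    "segments.csv: one row per transect segment.",
    "  segment_id, transect, length_km, region (gma|park_east|park_west),",
    "  side (east|west), area (gma|park), continuous covariates on raw",
    "  scales (edge_density km/km2, pct_* percent cover, lion_ud,",
    "  dist_road_km, dist_river_km, dist_stream_km), veg_class,",
    "  veg_class_simple, path_type.",
    "detections.csv: one row per detected herd per segment-survey.",
    "  species, segment_id, occasion, distance_m (perpendicular, m),",
    "  herd_size (individuals, >= 1), mixed_herd (0/1).",
    "occasions.csv: one row per segment x occasion.",
    "  segment_id, occasion, year, stage (early|mid|late), grass_height,",
    "  grass_color, water, burn, lagoon, occ_z (scaled occasion index).",
    "locations.csv: predator relocations. animal_id, fix, x, y (m).")
  writeLines(dict, file.path(dir, "data_dictionary.txt"))
  invisible(paths)
}

#' Read a pipeline configuration file
#'
#' YAML with fields: `species` (name -> truncation W in m), `cutpoint_width`
#' (m), `stepwise_alpha`, `delta_aic_window`, `n_boot`, `n_draw`, `seed`.
#' Missing fields take the defaults of [run_pipeline()].
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) stop("config must name at least one species")
  cfg
}

#' Run the full density pipeline on survey tables
#'
#' For each species: truncate detections; fit the herd-density model
#' (either a fixed formula set or the staged AIC selection); run the
#' deviance goodness-of-fit check; apply the herd-size detection-bias rule
#' and stepwise ZTP selection; compose per-segment population density;
#' bootstrap stratum means; and compute protection/year contrasts. Writes
#' CSV outputs plus a JSON manifest with seeds and configuration, so a run
#' is reproducible bit for bit.
#'
#' @param tables list from [read_survey_tables()] (or the same structure
#'   built in memory).
#' @param outdir output directory.
#' @param species named vector of truncation distances W (m) per species.
#' @param formula_lambda,formula_phi,formula_p fixed model formulas
#'   (used when `select = FALSE`).
#' @param key detection key for the fixed-formula route.
#' @param select run [staged_selection()] instead of fixed formulas.
#' @param pools candidate pools when `select = TRUE`.
#' @param size_terms candidate herd-size terms for [stepwise_select()].
#' @param stepwise_alpha,delta_aic_window,n_boot,n_draw,gof_boot tuning
#'   parameters.
#' @param on_line_tol distances at or below this (m) count as "on the line"
#'   for the herd-size bias rule; with continuously recorded distances a
#'   small positive tolerance stands in for the field convention of
#'   recording on-transect herds as 0 m.
#' @param seed integer seed controlling every stochastic step.
#' @return invisibly, a list of per-species results.
#' @export
run_pipeline <- function(tables, outdir, species,
                         formula_lambda = ~ area + side,
                         formula_phi = ~ year, formula_p = ~1,
                         key = "halfnorm", select = FALSE,
                         pools = hds_candidate_pools(),
                         size_terms = c("area", "side"),
                         stepwise_alpha = 0.05, delta_aic_window = 2,
                         n_boot = 1000, n_draw = 1000, gof_boot = 50,
                         on_line_tol = 10, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(species))) stop("`species` must be a named W vector")
  missing_sp <- setdiff(names(species), unique(tables$detections$species))
  if (length(missing_sp))
    stop("species not present in the detection table: ",
         paste(missing_sp, collapse = ", "))
  results <- list()
  for (sp in names(species)) {
    W <- species[[sp]]
    tr <- truncate_detections(
      tables$detections[tables$detections$species == sp, , drop = FALSE],
      stats::setNames(W, sp))
    hd <- hds_data(tr$detections, tables$segments, tables$occasions, W = W)
    if (select) {
      sel <- staged_selection(hd, pools = pools)
      fit <- best_model(sel$final)
      utils::write.csv(sel$final$table,
                       file.path(outdir, paste0(sp, "_ranking.csv")),
                       row.names = FALSE)
      lam_hat <- model_average(sel$final, window = delta_aic_window)$estimate
    } else {
      sel <- NULL
      fit <- fit_hds(hd, formula_lambda, formula_phi, formula_p, key = key)
      lam_hat <- predict_hds(fit, type = "lambda")$estimate
    }
    gof <- deviance_gof(fit, n_boot = gof_boot, seed = seed + 11L)
    # herd size: bias rule then stepwise selection
    det_cov <- merge(tr$detections, tables$segments, by = "segment_id",
                     sort = FALSE)
    if (!is.null(tables$occasions))
      det_cov <- merge(det_cov, tables$occasions,
                       by = c("segment_id", "occasion"), sort = FALSE)
    bias <- size_bias_test(det_cov, on_line_tol = on_line_tol)
    step <- stepwise_select(bias$detections,
                            intersect(size_terms, names(det_cov)),
                            alpha = stepwise_alpha)
    resid_ck <- residual_fit_check(step$fit)
    rng <- observed_ranges(bias$detections,
                           intersect(step$kept, names(bias$detections)))
    # per-segment composition
    seg_cov <- tables$segments
    phi_bar <- if (is.null(fit$model$phi)) fit$fix_phi
               else mean(predict_hds(fit, type = "phi")$estimate)
    size_pred <- predict_group_size(step$fit, det_cov_means(seg_cov, det_cov,
                                                           step$kept), rng)
    surface <- data.frame(segment_id = seg_cov$segment_id,
                          region = seg_cov$region,
                          herd_density = lam_hat * phi_bar,
                          mean_size = size_pred$mean_size)
    surface$density <- surface$herd_density * surface$mean_size
    strat <- bootstrap_strata(surface, strata = "region", n_boot = n_boot,
                              seed = seed + 17L)
    contr <- counterfactual_contrasts(fit, step$fit, n_draw = n_draw,
                                      seed = seed + 23L)
    utils::write.csv(data.frame(term = names(fit$coef), estimate = fit$coef,
                                se = fit$se),
                     file.path(outdir, paste0(sp, "_hds_coef.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(term = names(step$fit$coef),
                                estimate = step$fit$coef, se = step$fit$se,
                                change = exp(step$fit$coef)),
                     file.path(outdir, paste0(sp, "_size_coef.csv")),
                     row.names = FALSE)
    utils::write.csv(surface, file.path(outdir, paste0(sp, "_density.csv")),
                     row.names = FALSE)
    utils::write.csv(strat, file.path(outdir, paste0(sp, "_strata.csv")),
                     row.names = FALSE)
    utils::write.csv(contr$region_contrasts,
                     file.path(outdir, paste0(sp, "_contrasts.csv")),
                     row.names = FALSE)
    results[[sp]] <- list(truncation = tr$counts, fit = fit, gof = gof,
                          size = step, residual_check = resid_ck,
                          surface = surface, strata = strat,
                          contrasts = contr, selection = sel)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("herddensity")),
    r_version = R.version.string,
    seed = seed,
    species = as.list(species),
    settings = list(stepwise_alpha = stepwise_alpha,
                    delta_aic_window = delta_aic_window,
                    n_boot = n_boot, n_draw = n_draw, gof_boot = gof_boot,
                    select = select),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# segment-level prediction frame for herd size: segment covariates plus
# herd-level covariates fixed at reference/mean values from the herds
det_cov_means <- function(segments, det_cov, vars) {
  nd <- segments
  for (v in setdiff(vars, names(nd))) {
    x <- det_cov[[v]]
    if (is.null(x)) next
    nd[[v]] <- if (is.numeric(x)) mean(x)
               else factor(names(which.max(table(x))),
                           levels = levels(factor(x)))
  }
  nd
}
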