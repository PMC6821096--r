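# Staged AIC model selection for the distance-sampling analysis.
#
# Detection is selected first (all combinations of its covariates under
# hazard, half-normal and uniform keys, with intercept-only availability
# and super-population), then availability with detection fixed at its
# winner, then the super-population covariates in separate typed pools
# (abiotic, edge density, top-down, vegetation availability,
# anthropogenic), and finally all additive combinations of the per-type
# winners. Predictions are averaged over models within a delta-AIC window
# using Akaike weights.

#' Akaike's information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters (>= 1).
#' @return `-2 loglik + 2 n_params`.
#' @export
aic <- function(loglik, n_params) {
  if (any(n_params < 1)) stop("`n_params` must be at least 1")
  -2 * loglik + 2 * n_params
}

#' Akaike weights over a model set
#'
#' @param aic_values vector of AIC scores.
#' @return weights `exp(-delta/2) / sum(exp(-delta/2))`; they sum to 1 and
#'   are invariant to adding a constant to every AIC.
#' @export
akaike_weights <- function(aic_values) {
  delta <- aic_values - min(aic_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Screen covariates for collinearity and imbalance
#'
#' Among continuous covariate pairs with `|r|` above `r_threshold`
#' (default 0.6), the member explaining less marginal variance in the
#' per-segment detection counts (lower squared correlation with counts) is
#' dropped; the rule is deterministic and reported. Categorical covariates
#' with any level observed fewer than `min_level_n` times are flagged as
#' imbalanced and dropped.
#'
#' @param segments segment covariate table.
#' @param detections detection table (used to build the per-segment count
#'   response for the marginal-variance rule).
#' @param covariates covariate names to screen; default: all covariate
#'   columns of `segments`.
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   collinear.
#' @param min_level_n minimum observations per categorical level.
#' @return list: `retained`, `dropped`, `report` (data.frame).
#' @export
screen_covariates <- function(segments, detections, covariates = NULL,
                              r_threshold = 0.6, min_level_n = 5) {
  skip <- c("segment_id", "transect", "length_km")
  covariates <- covariates %||% setdiff(names(segments), skip)
  counts <- table(factor(detections$segment_id, levels = segments$segment_id))
  counts <- as.numeric(counts)
  is_num <- vapply(covariates, function(v) is.numeric(segments[[v]]), TRUE)
  report <- list()
  dropped <- character()
  # categorical imbalance
  for (v in covariates[!is_num]) {
    tab <- table(segments[[v]])
    if (any(tab < min_level_n)) {
      dropped <- c(dropped, v)
      report[[length(report) + 1L]] <- data.frame(
        covariate = v, reason = "imbalanced",
        detail = sprintf("min level count %d < %d", min(tab), min_level_n))
    }
  }
  # collinearity among continuous, iterated to a fixed point
  cont <- setdiff(covariates[is_num], dropped)
  r2_resp <- vapply(cont, function(v)
    suppressWarnings(stats::cor(segments[[v]], counts))^2, numeric(1))
  r2_resp[is.na(r2_resp)] <- 0
  repeat {
    if (length(cont) < 2) break
    cm <- abs(suppressWarnings(stats::cor(segments[cont])))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= r_threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- cont[ij]
    loser <- pair[which.min(r2_resp[pair])]
    report[[length(report) + 1L]] <- data.frame(
      covariate = loser, reason = "collinear",
      detail = sprintf("|r| = %.3f with %s", max(cm), setdiff(pair, loser)[1]))
    dropped <- c(dropped, loser)
    cont <- setdiff(cont, loser)
  }
  list(retained = setdiff(covariates, dropped), dropped = dropped,
       report = if (length(report)) do.call(rbind, report)
                else data.frame(covariate = character(), reason = character(),
                                detail = character()))
}

# expand a covariate into its candidate functional forms
term_forms <- function(v, frame, forms = c("linear", "log", "poly")) {
  if (!is.numeric(frame[[v]])) return(v)
  out <- character()
  if ("linear" %in% forms) out <- c(out, v)
  if ("log" %in% forms) out <- c(out, paste0("log_", v))
  if ("poly" %in% forms) out <- c(out, sprintf("poly(%s, 2)", v))
  out
}

# all formulas from a pool: each covariate absent or in one functional form
enumerate_pool <- function(pool, frame, forms = c("linear", "log", "poly"),
                           max_terms = Inf) {
  if (!length(pool)) return("~1")
  options <- lapply(pool, function(v) c(NA_character_, term_forms(v, frame, forms)))
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  fs <- apply(grid, 1, function(row) {
    terms <- row[!is.na(row)]
    if (length(terms) > max_terms) return(NA_character_)
    if (!length(terms)) "~1" else paste("~", paste(terms, collapse = " + "))
  })
  unique(fs[!is.na(fs)])
}

fit_candidate <- function(data, f_lam, f_phi, f_p, key, fix_phi = NULL) {
  tryCatch(
    suppressWarnings(fit_hds(data,
      formula_lambda = stats::as.formula(f_lam),
      formula_phi = stats::as.formula(f_phi),
      formula_p = stats::as.formula(f_p),
      key = key, fix_phi = fix_phi)),
    error = function(e) NULL)
}

# assemble a ranked candidate set; deterministic tie-break: AIC, then fewer
# parameters, then lexicographic formula label
candidate_set <- function(stage, labels, fits) {
  keep <- !vapply(fits, is.null, TRUE)
  keep[keep] <- vapply(fits[keep], function(f) isTRUE(f$converged), TRUE)
  excluded <- labels[!keep]
  fits <- fits[keep]; labels <- labels[keep]
  if (!length(fits)) stop("no converged candidates in stage ", stage)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$n_par, numeric(1))
  ord <- order(aics, k, labels)
  fits <- fits[ord]; labels <- labels[ord]; aics <- aics[ord]; k <- k[ord]
  tab <- data.frame(model = labels, n_par = k,
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    aic = aics, delta_aic = aics - min(aics),
                    weight = akaike_weights(aics),
                    row.names = NULL)
  structure(list(stage = stage, table = tab, fits = fits,
                 excluded = excluded),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set [%s]: %d converged model(s)\n", x$stage,
              nrow(x$table)))
  print(transform(x$table, loglik = round(loglik, 2), aic = round(aic, 2),
                  delta_aic = round(delta_aic, 2), weight = round(weight, 3)))
  invisible(x)
}

#' Top-ranked model of a candidate set
#'
#' @param cset a `candidate_set`.
#' @return `best_model()`: the AIC-best `hds_fit`; `best_label()`: its
#'   formula label.
#' @export
best_model <- function(cset) cset$fits[[1]]

#' @rdname best_model
#' @export
best_label <- function(cset) cset$table$model[1]

#' Default covariate pools for the staged selection
#'
#' Mirrors the full-model structure of the survey analysis: detection from
#' vegetation class (full or simplified, never both) and path type;
#' availability from dry-season stage, year, grass height, grass colour,
#' burn, lagoon and water; and super-population pools split by effect type
#' (abiotic, edge density, top-down, vegetation availability,
#' anthropogenic).
#'
#' @export
hds_candidate_pools <- function() {
  list(
    detection = list(veg = c("veg_class", "veg_class_simple"),
                     other = "path_type"),
    availability = c("stage", "year", "grass_height", "grass_color",
                     "burn", "lagoon", "water"),
    lambda = list(
      abiotic = c("dist_river_km", "dist_stream_km"),
      edge = "edge_density",
      topdown = "lion_ud",
      vegetation = c("pct_closed_scrub", "pct_closed_woodland",
                     "pct_open_woodland", "pct_open_grassland"),
      anthropogenic = c("dist_road_km", "area", "side")
    )
  )
}

#' Three-step AIC model selection
#'
#' Step 1 fits every combination of detection covariates (the two
#' vegetation-class descriptions are alternatives, never combined) under
#' each detection key, with intercept-only availability and
#' super-population, and keeps the AIC-best. Step 2 fixes detection and
#' fits all subsets of the availability pool. Step 3 fixes both and fits
#' each super-population pool separately (continuous covariates enter as
#' linear, log or orthogonal-quadratic terms), then ranks all additive
#' combinations of the per-type winning term blocks. Non-converged
#' candidates are excluded and listed.
#'
#' @param data an [hds_data()] object.
#' @param pools covariate pools, see [hds_candidate_pools()].
#' @param keys detection keys to consider.
#' @param forms functional forms for continuous covariates.
#' @param max_terms cap on the number of terms per candidate formula.
#' @return list of `candidate_set`s: `detection`, `availability`, one per
#'   lambda pool, and `final`.
#' @export
staged_selection <- function(data, pools = hds_candidate_pools(),
                             keys = c("halfnorm", "hazard", "uniform"),
                             forms = c("linear", "log", "poly"),
                             max_terms = 4) {
  seg <- data$segments
  occ <- data$occasions
  # --- step 1: detection ---------------------------------------------------
  veg_opts <- c(NA_character_, pools$detection$veg)
  path_opts <- c(NA_character_, pools$detection$other)
  labels <- character(); specs <- list()
  for (key in keys) {
    if (key == "uniform") {
      labels <- c(labels, "uniform ~1")
      specs[[length(specs) + 1L]] <- list(key = key, f_p = "~1")
      next
    }
    for (v in veg_opts) for (pt in path_opts) {
      terms <- c(v, pt); terms <- terms[!is.na(terms)]
      f_p <- if (length(terms)) paste("~", paste(terms, collapse = " + ")) else "~1"
      labels <- c(labels, paste(key, f_p))
      specs[[length(specs) + 1L]] <- list(key = key, f_p = f_p)
    }
  }
  fits <- lapply(specs, function(s)
    fit_candidate(data, "~1", "~1", s$f_p, s$key))
  det_set <- candidate_set("detection", labels, fits)
  det_best <- specs[[match(best_label(det_set), labels)]]
  # --- step 2: availability ------------------------------------------------
  phi_formulas <- enumerate_pool(pools$availability, occ, forms = "linear",
                                 max_terms = max_terms)
  fits <- lapply(phi_formulas, function(f)
    fit_candidate(data, "~1", f, det_best$f_p, det_best$key))
  phi_set <- candidate_set("availability", phi_formulas, fits)
  phi_best <- best_label(phi_set)
  # --- step 3: typed lambda pools ------------------------------------------
  pool_sets <- list()
  winners <- list()
  for (pool_name in names(pools$lambda)) {
    lam_formulas <- enumerate_pool(pools$lambda[[pool_name]], seg,
                                   forms = forms, max_terms = max_terms)
    fits <- lapply(lam_formulas, function(f)
      fit_candidate(data, f, phi_best, det_best$f_p, det_best$key))
    cs <- candidate_set(paste0("abundance_", pool_name), lam_formulas, fits)
    pool_sets[[pool_name]] <- cs
    win <- best_label(cs)
    winners[[pool_name]] <-
      if (identical(win, "~1")) character()
      else trimws(strsplit(sub("^~\\s*", "", win), "\\+")[[1]])
  }
  # --- final: all additive combinations of per-type winner blocks ----------
  blocks <- winners[vapply(winners, length, 1L) > 0]
  if (!length(blocks)) {
    final_formulas <- "~1"
  } else {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(blocks)))
    final_formulas <- unique(apply(combos, 1, function(inc) {
      terms <- unlist(blocks[as.logical(inc)], use.names = FALSE)
      if (!length(terms)) "~1" else paste("~", paste(terms, collapse = " + "))
    }))
  }
  fits <- lapply(final_formulas, function(f)
    fit_candidate(data, f, phi_best, det_best$f_p, det_best$key))
  final_set <- candidate_set("final", final_formulas, fits)
  c(list(detection = det_set, availability = phi_set), pool_sets,
    list(final = final_set))
}

#' Model-averaged predictions over a delta-AIC window
#'
#' Akaike weights are computed over the models whose delta AIC does not
#' exceed `window` (the best model is always included); herd-density and
#' availability predictions are averaged with those weights.
#'
#' @param cset a `candidate_set`.
#' @param newdata covariates on the raw scale (`NULL`: fitting frames).
#' @param window delta-AIC window (default 2).
#' @param type `"lambda"` or `"phi"`.
#' @return list: `estimate` (averaged predictions), `weights` (named),
#'   `models` (labels used).
#' @export
model_average <- function(cset, newdata = NULL, window = 2,
                          type = c("lambda", "phi")) {
  type <- match.arg(type)
  stopifnot(inherits(cset, "candidate_set"))
  in_win <- which(cset$table$delta_aic <= window)
  w <- akaike_weights(cset$table$aic[in_win])
  preds <- lapply(cset$fits[in_win], function(f)
    predict_hds(f, newdata = newdata, type = type)$estimate)
  est <- Reduce(`+`, Map(`*`, preds, w))
  list(estimate = est,
       weights = stats::setNames(w, cset$table$model[in_win]),
       models = cset$table$model[in_win])
}
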