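# Synthetic line-transect surveys with known ground truth.
#
# The generator emulates the study conditions of a stratified dry-season
# ground-transect programme: 15 transects split into 97 segments (maximum
# segment length 2 km) across three protection regions (fully protected
# parklands west and east of a river, and a partially protected GMA), with
# 10 survey occasions spread over four years and three dry-season stages.
# Herds arise from a covariate-linked Poisson super-population per
# segment-occasion, are thinned by availability, placed uniformly in
# perpendicular distance inside the truncation strip, detected according to
# a distance function, and assigned zero-truncated Poisson sizes.

# Static segment covariates: observed range and mean on the raw scale.
# Continuous draws use a scaled Beta matched to the stated mean
# (concentration 4), which reproduces the skew of the bounded covariates.
.covariate_ranges <- list(
  edge_density       = c(3.5, 55.6, 24.4),
  pct_closed_scrub   = c(0.0, 38.0, 2.3),
  pct_closed_woodland = c(0.0, 90.8, 23.4),
  pct_open_woodland  = c(0.5, 96.3, 37.7),
  pct_open_grassland = c(0.0, 99.5, 36.7),
  lion_ud            = c(6.0, 121.1, 49.0),
  dist_road_km       = c(0.0, 2.4, 0.3),
  dist_river_km      = c(0.2, 14.7, 4.1),
  dist_stream_km     = c(0.0, 9.4, 3.4)
)

.veg_levels <- c("closed_scrub", "closed_woodland", "open_scrub",
                 "open_woodland", "open_grassland_flooded",
                 "open_grassland_not_flooded")
.veg_simple_map <- c(closed_scrub = "scrub", open_scrub = "scrub",
                     closed_woodland = "woodland", open_woodland = "woodland",
                     open_grassland_flooded = "grassland",
                     open_grassland_not_flooded = "grassland")
.path_levels <- c("off_road", "seasonal_track", "gravel_road")
.region_levels <- c("gma", "park_east", "park_west")

draw_range_beta <- function(n, a, b, m, concentration = 4) {
  mu <- (m - a) / (b - a)
  a + (b - a) * stats::rbeta(n, mu * concentration, (1 - mu) * concentration)
}

#' Generate a stratified line-transect survey design
#'
#' Builds a segment table with region labels assigned in transect blocks and
#' static covariates drawn from their documented ranges. Segment lengths are
#' uniform on (0.5, `max_segment_length_km`] km, respecting the 2 km maximum
#' segment length of the survey protocol.
#'
#' @param n_transects number of transects (>= 1).
#' @param segments_per_transect integer scalar or length-`n_transects`
#'   vector of segment counts.
#' @param seed integer seed; identical seeds give byte-identical designs.
#' @param region_by_transect character vector (length `n_transects`) of
#'   region labels (`"park_west"`, `"park_east"`, `"gma"`); default splits
#'   transects across the three regions proportionally.
#' @param max_segment_length_km maximum segment length (km), default 2.
#' @param truncation_w_m strip half-width W (m) used when simulating.
#' @param n_occasions number of survey occasions.
#' @return object of class `survey_design`: list with `segments`
#'   (data.frame), `n_occasions`, `truncation_w_m`.
#' @export
generate_design <- function(n_transects, segments_per_transect, seed = NULL,
                            region_by_transect = NULL,
                            max_segment_length_km = 2,
                            truncation_w_m = 300, n_occasions = 10) {
  stop_if_not_count(n_transects, "n_transects")
  stop_if_not_count(segments_per_transect, "segments_per_transect")
  if (max_segment_length_km <= 0 || max_segment_length_km > 2)
    stop("`max_segment_length_km` must lie in (0, 2]")
  if (length(segments_per_transect) == 1L)
    segments_per_transect <- rep(segments_per_transect, n_transects)
  if (length(segments_per_transect) != n_transects)
    stop("`segments_per_transect` must have length 1 or `n_transects`")
  if (is.null(region_by_transect)) {
    # proportional block assignment: west parklands get the most transects
    n_pw <- max(1L, round(n_transects * 0.6))
    n_pe <- max(1L, round(n_transects * 0.15))
    if (n_pw + n_pe >= n_transects) { n_pw <- max(1L, n_transects - 2L); n_pe <- 1L }
    n_g <- n_transects - n_pw - n_pe
    region_by_transect <- rep(c("park_west", "park_east", "gma"),
                              times = c(n_pw, n_pe, max(n_g, 0L)))[seq_len(n_transects)]
  }
  if (length(region_by_transect) != n_transects ||
      !all(region_by_transect %in% .region_levels))
    stop("`region_by_transect` must give a valid region per transect")

  with_seed(seed, {
    S <- sum(segments_per_transect)
    transect <- rep(seq_len(n_transects), segments_per_transect)
    region <- factor(region_by_transect[transect], levels = .region_levels)
    seg <- data.frame(
      segment_id = sprintf("s%03d", seq_len(S)),
      transect = transect,
      length_km = stats::runif(S, 0.5, max_segment_length_km),
      region = region,
      side = factor(ifelse(region == "park_west", "west", "east"),
                    levels = c("east", "west")),
      area = factor(ifelse(region == "gma", "gma", "park"),
                    levels = c("gma", "park")),
      stringsAsFactors = FALSE
    )
    for (nm in names(.covariate_ranges)) {
      r <- .covariate_ranges[[nm]]
      seg[[nm]] <- draw_range_beta(S, r[1], r[2], r[3])
    }
    seg$veg_class <- factor(sample(.veg_levels, S, replace = TRUE),
                            levels = .veg_levels)
    seg$veg_class_simple <- factor(.veg_simple_map[as.character(seg$veg_class)],
                                   levels = c("scrub", "woodland", "grassland"))
    seg$path_type <- factor(
      sample(.path_levels, S, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      levels = .path_levels)
    structure(list(segments = seg, n_occasions = as.integer(n_occasions),
                   truncation_w_m = truncation_w_m),
              class = "survey_design")
  })
}

#' Study-scale survey design (15 transects, 97 segments)
#'
#' Convenience wrapper reproducing the study geometry: 97 segments over 15
#' transects, with 62 segments in western parklands, 15 east of the river in
#' the park, and 20 in the GMA.
#'
#' @inheritParams generate_design
#' @export
slpg_design <- function(seed = NULL, truncation_w_m = 300, n_occasions = 10) {
  segs <- c(rep(7L, 8), 6L,      # park_west: 62
            8L, 7L,              # park_east: 15
            rep(5L, 4))          # gma: 20
  regions <- c(rep("park_west", 9), rep("park_east", 2), rep("gma", 4))
  generate_design(15L, segs, seed = seed, region_by_transect = regions,
                  truncation_w_m = truncation_w_m, n_occasions = n_occasions)
}

# survey calendar for the default 10 occasions: 2012-2015, three dry-season
# stages per year, with the first-early and last-middle surveys missing
.occasion_schedule <- data.frame(
  occasion = 1:10,
  year = factor(c(2012, 2012, 2013, 2013, 2013, 2014, 2014, 2014, 2015, 2015),
                levels = c(2012, 2013, 2014, 2015)),
  stage = factor(c("mid", "late", "early", "mid", "late",
                   "early", "mid", "late", "early", "late"),
                 levels = c("early", "mid", "late"))
)

#' Generate per-occasion dynamic covariates
#'
#' One row per segment x occasion: survey year and dry-season stage follow
#' the default 10-occasion calendar (truncated or recycled for other
#' occasion counts); grass height, grass colour, standing water, burn
#' evidence and grassy-lagoon presence are categorical draws with
#' configurable probabilities (uniform by default).
#'
#' @param design a `survey_design`.
#' @param seed integer seed.
#' @param probs optional named list of level-probability vectors for
#'   `grass_height`, `grass_color`, `water`, `burn`, `lagoon`.
#' @return data.frame keyed by (`segment_id`, `occasion`).
#' @export
generate_occasions <- function(design, seed = NULL, probs = list()) {
  stopifnot(inherits(design, "survey_design"))
  S <- nrow(design$segments)
  T_ <- design$n_occasions
  sched <- .occasion_schedule[((seq_len(T_) - 1L) %% 10L) + 1L, ]
  p <- utils::modifyList(list(
    grass_height = c(short = 1, intermediate = 1, long = 1) / 3,
    grass_color  = c(brown = 1, green = 1) / 2,
    water        = c(absent = 1, present = 1) / 2,
    burn         = c(absent = 1, present = 1) / 2,
    lagoon       = c(absent = 1, present = 1) / 2
  ), probs)
  with_seed(seed, {
    n <- S * T_
    occ <- data.frame(
      segment_id = rep(design$segments$segment_id, times = T_),
      occasion = rep(seq_len(T_), each = S),
      year = rep(sched$year, each = S),
      stage = rep(sched$stage, each = S)
    )
    draw <- function(pv) factor(sample(names(pv), n, TRUE, prob = pv),
                                levels = names(pv))
    occ$grass_height <- draw(p$grass_height)
    occ$grass_color <- draw(p$grass_color)
    occ$water <- draw(p$water)
    occ$burn <- draw(p$burn)
    occ$lagoon <- draw(p$lagoon)
    # continuous occasion index (scaled) for simple availability truths
    occ$occ_z <- as.numeric(scale(occ$occasion))
    occ
  })
}

#' Ground-truth parameters for survey simulation
#'
#' Bundles the true herd super-population model (log link, herds/km^2), the
#' availability model (logit link), the detection function and the
#' zero-truncated Poisson herd-size model (log link) used by
#' [simulate_survey()]. Formulas are evaluated on the raw covariate scale.
#'
#' Defaults describe a realistic mid-density ungulate: about 2 herds/km^2 in
#' the GMA with an e-fold park effect, availability rising toward saturation
#' as the dry season progresses (which also identifies the lambda/phi split),
#' a 100 m half-normal detection scale, and mean herd size around 5.
#'
#' @param formula_lambda,beta_lambda super-population model and coefficients.
#' @param formula_phi,beta_phi availability model and coefficients.
#' @param key,sigma,b detection function (see [detection_prob()]).
#' @param formula_size,beta_size herd-size model and coefficients.
#' @param mixed_prob probability a detected herd is a mixed-species herd;
#'   `mixed_beta` is its log-scale effect on herd size.
#' @param seed default seed consumed by [simulate_survey()].
#' @export
truth_params <- function(formula_lambda = ~ area, beta_lambda = c(log(2), 1),
                         formula_phi = ~ occ_z, beta_phi = c(1.0, 1.5),
                         key = "halfnorm", sigma = 100, b = NULL,
                         formula_size = ~ 1, beta_size = log(5),
                         mixed_prob = 0.15, mixed_beta = 0, seed = NULL) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (identical(key, "hazard") && (is.null(b) || b <= 0))
    stop("hazard key requires shape `b` > 0")
  structure(list(formula_lambda = formula_lambda, beta_lambda = beta_lambda,
                 formula_phi = formula_phi, beta_phi = beta_phi,
                 key = key, sigma = sigma, b = b,
                 formula_size = formula_size, beta_size = beta_size,
                 mixed_prob = mixed_prob, mixed_beta = mixed_beta,
                 seed = seed),
            class = "truth_params")
}

# ZTP random draws by inverse cdf conditioned on k >= 1
rztpois <- function(n, mu) {
  mu <- rep_len(mu, n)
  p0 <- exp(-mu)
  u <- stats::runif(n)
  k <- stats::qpois(p0 + u * (1 - p0), mu)
  pmax(k, 1L)
}

#' Simulate detections from a line-transect survey
#'
#' For each segment-occasion the herd super-population is drawn
#' `N ~ Poisson(lambda_i * A_i)` with strip area `A_i = 2 W L_i` (km^2);
#' each herd is available with probability `phi_it`, placed uniformly in
#' perpendicular distance on `[0, W]`, detected with probability `g(x)`,
#' and given a zero-truncated Poisson size. Only detected herds are
#' returned, with their continuous distances.
#'
#' @param design a `survey_design`.
#' @param occasions occasion covariate table from [generate_occasions()].
#' @param truth a `truth_params` object.
#' @param species species label attached to the rows.
#' @param seed integer seed (defaults to `truth$seed`).
#' @return data.frame: `species`, `segment_id`, `occasion`, `distance_m`,
#'   `herd_size`, `mixed_herd`.
#' @export
simulate_survey <- function(design, occasions, truth, species = "impala",
                            seed = truth$seed) {
  stopifnot(inherits(design, "survey_design"), inherits(truth, "truth_params"))
  seg <- design$segments
  W <- design$truncation_w_m
  X_lam <- stats::model.matrix(truth$formula_lambda, seg)
  if (ncol(X_lam) != length(truth$beta_lambda))
    stop("`beta_lambda` length does not match the lambda model matrix")
  lam <- exp(drop(X_lam %*% truth$beta_lambda))          # herds/km^2
  area <- 2 * (W / 1000) * seg$length_km                 # km^2
  occ <- occasions[order(occasions$occasion,
                         match(occasions$segment_id, seg$segment_id)), ]
  X_phi <- stats::model.matrix(truth$formula_phi, occ)
  if (ncol(X_phi) != length(truth$beta_phi))
    stop("`beta_phi` length does not match the phi model matrix")
  phi <- stats::plogis(drop(X_phi %*% truth$beta_phi))
  occ_full <- merge(occ, seg, by = "segment_id", sort = FALSE)
  occ_full <- occ_full[order(occ_full$occasion,
                             match(occ_full$segment_id, seg$segment_id)), ]
  X_size <- stats::model.matrix(truth$formula_size, occ_full)
  if (ncol(X_size) != length(truth$beta_size))
    stop("`beta_size` length does not match the size model matrix")
  mu_size <- exp(drop(X_size %*% truth$beta_size))

  with_seed(seed, {
    idx_seg <- match(occ$segment_id, seg$segment_id)
    mean_N <- lam[idx_seg] * area[idx_seg]
    N <- stats::rpois(length(mean_N), mean_N)
    if (sum(N) == 0)
      return(data.frame(species = character(), segment_id = character(),
                        occasion = integer(), distance_m = numeric(),
                        herd_size = integer(), mixed_herd = integer()))
    row_of <- rep(seq_along(N), N)
    avail <- stats::runif(sum(N)) < phi[row_of]
    x <- stats::runif(sum(N), 0, W)
    g <- detection_prob(truth$key, x, sigma = truth$sigma, b = truth$b)
    det <- avail & (stats::runif(sum(N)) < g)
    keep <- which(det)
    if (!length(keep))
      return(data.frame(species = character(), segment_id = character(),
                        occasion = integer(), distance_m = numeric(),
                        herd_size = integer(), mixed_herd = integer()))
    rows <- row_of[keep]
    mixed <- as.integer(stats::runif(length(keep)) < truth$mixed_prob)
    mu_k <- mu_size[rows] * exp(truth$mixed_beta * mixed)
    data.frame(
      species = species,
      segment_id = occ$segment_id[rows],
      occasion = occ$occasion[rows],
      distance_m = x[keep],
      herd_size = rztpois(length(keep), mu_k),
      mixed_herd = mixed,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate predator relocation fixes
#'
#' Mean-reverting correlated random walk per animal around its activity
#' centre: `x_t = c + rho (x_{t-1} - c) + N(0, step_scale^2)`, one fix per
#' day. Daily displacement distances for bandwidth estimation come from
#' consecutive fixes via [daily_displacements()].
#'
#' @param n_animals,n_fixes counts (>= 1).
#' @param step_scale_m innovation SD of the walk (m).
#' @param centers matrix (`n_animals` x 2) of activity centres (m); a single
#'   row is recycled.
#' @param seed integer seed.
#' @param rho autocorrelation of the walk in (0, 1).
#' @return data.frame: `animal_id`, `fix`, `x`, `y`.
#' @export
simulate_relocations <- function(n_animals, n_fixes, step_scale_m, centers,
                                 seed = NULL, rho = 0.6) {
  stop_if_not_count(n_animals, "n_animals")
  stop_if_not_count(n_fixes, "n_fixes")
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) == 1L) centers <- centers[rep(1, n_animals), , drop = FALSE]
  if (nrow(centers) != n_animals) stop("`centers` must have one row per animal")
  with_seed(seed, {
    out <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      xy <- matrix(0, n_fixes, 2)
      xy[1, ] <- centers[a, ] + stats::rnorm(2, 0, step_scale_m)
      if (n_fixes > 1) for (t in 2:n_fixes) {
        xy[t, ] <- centers[a, ] + rho * (xy[t - 1, ] - centers[a, ]) +
          stats::rnorm(2, 0, step_scale_m)
      }
      out[[a]] <- data.frame(animal_id = a, fix = seq_len(n_fixes),
                             x = xy[, 1], y = xy[, 2])
    }
    do.call(rbind, out)
  })
}

#' Daily displacement distances from consecutive fixes
#'
#' @param locations relocation table from [simulate_relocations()].
#' @return numeric vector of per-animal consecutive-fix distances (m).
#' @export
daily_displacements <- function(locations) {
  unlist(lapply(split(locations, locations$animal_id), function(d) {
    d <- d[order(d$fix), ]
    if (nrow(d) < 2) return(numeric())
    sqrt(diff(d$x)^2 + diff(d$y)^2)
  }), use.names = FALSE)
}
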