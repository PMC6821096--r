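# Predator-risk surface: a bivariate-normal kernel utilization distribution
# over pooled relocations, gridded and sampled at segment midpoints.

#' Movement-percentile smoothing bandwidth
#'
#' The kernel bandwidth is a percentile of the empirical daily-displacement
#' distribution (default the 90th), computed with linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param daily_displacements nonnegative displacement distances (m).
#' @param percentile percentile in \[0, 100\], default 90.
#' @return bandwidth h (m).
#' @export
smoothing_bandwidth <- function(daily_displacements, percentile = 90) {
  if (!length(daily_displacements)) stop("no displacement distances supplied")
  if (any(daily_displacements < 0)) stop("displacements must be nonnegative")
  unname(stats::quantile(daily_displacements, percentile / 100, type = 7))
}

#' Bivariate-normal kernel utilization distribution on a grid
#'
#' Each cell value is the average over relocations of the isotropic
#' bivariate normal kernel with SD `h`, evaluated at the cell centre, then
#' normalized so the grid integrates to 1 (`sum(values) * cell_area = 1`).
#' All animals' fixes are pooled with equal weight. The default extent is
#' the bounding box of the locations padded by `4 h`; a supplied extent not
#' covering all locations is expanded with a warning.
#'
#' @param locations data.frame with `x`, `y` (m).
#' @param h kernel SD (m), > 0.
#' @param cell_size grid resolution (m), default 300.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`.
#' @return object of class `ud_grid`: `values` (matrix, rows = x index,
#'   cols = y index), `x`, `y` (cell-centre coordinates), `cell_size`.
#' @export
kernel_ud <- function(locations, h, cell_size = 300, extent = NULL) {
  if (h <= 0) stop("`h` must be positive")
  if (!nrow(locations)) stop("at least one location is required")
  pad <- 4 * h
  bbox <- c(min(locations$x) - pad, max(locations$x) + pad,
            min(locations$y) - pad, max(locations$y) + pad)
  if (is.null(extent)) {
    extent <- bbox
  } else if (extent[1] > min(locations$x) || extent[2] < max(locations$x) ||
             extent[3] > min(locations$y) || extent[4] < max(locations$y)) {
    warning("extent does not cover all locations; expanding")
    extent <- c(min(extent[1], bbox[1]), max(extent[2], bbox[2]),
                min(extent[3], bbox[3]), max(extent[4], bbox[4]))
  }
  x <- seq(extent[1] + cell_size / 2, extent[2], by = cell_size)
  y <- seq(extent[3] + cell_size / 2, extent[4], by = cell_size)
  # outer sums of 1-d kernels: density_xy = mean_i phi(x - xi) phi(y - yi)
  Kx <- outer(x, locations$x, function(a, b) stats::dnorm(a - b, sd = h))
  Ky <- outer(y, locations$y, function(a, b) stats::dnorm(a - b, sd = h))
  vals <- (Kx %*% t(Ky)) / nrow(locations)
  vals <- vals / (sum(vals) * cell_size^2)
  structure(list(values = vals, x = x, y = y, cell_size = cell_size),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("Kernel UD grid: %d x %d cells of %g m; integral %.6f\n",
              length(x$x), length(x$y), x$cell_size,
              sum(x$values) * x$cell_size^2))
  invisible(x)
}

# bilinear interpolation of the grid at arbitrary points
bilinear_at <- function(grid, px, py) {
  ix <- findInterval(px, grid$x, all.inside = TRUE)
  iy <- findInterval(py, grid$y, all.inside = TRUE)
  x1 <- grid$x[ix]; x2 <- grid$x[ix + 1]
  y1 <- grid$y[iy]; y2 <- grid$y[iy + 1]
  tx <- pmin(pmax((px - x1) / (x2 - x1), 0), 1)
  ty <- pmin(pmax((py - y1) / (y2 - y1), 0), 1)
  v11 <- grid$values[cbind(ix, iy)]
  v21 <- grid$values[cbind(ix + 1, iy)]
  v12 <- grid$values[cbind(ix, iy + 1)]
  v22 <- grid$values[cbind(ix + 1, iy + 1)]
  (1 - tx) * (1 - ty) * v11 + tx * (1 - ty) * v21 +
    (1 - tx) * ty * v12 + tx * ty * v22
}

#' Sample and standardize UD values at points
#'
#' Bilinearly samples the UD grid at each point (segment midpoints in the
#' pipeline) and z-scores the extracted set (mean 0, SD 1 with the n-1
#' convention). Raw values are returned alongside, since the raw scale is
#' what the covariate summaries report. A zero-variance extraction yields
#' `NaN` standardized values with a warning.
#'
#' @param grid a `ud_grid`.
#' @param points data.frame with `x`, `y`; must lie inside the grid extent.
#' @return data.frame: `raw`, `standardized`.
#' @export
extract_standardized <- function(grid, points) {
  half <- grid$cell_size / 2
  out_x <- points$x < grid$x[1] - half | points$x > grid$x[length(grid$x)] + half
  out_y <- points$y < grid$y[1] - half | points$y > grid$y[length(grid$y)] + half
  if (any(out_x | out_y))
    stop("points outside grid extent at indices: ",
         paste(which(out_x | out_y), collapse = ", "))
  raw <- bilinear_at(grid, points$x, points$y)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    warning("zero variance among extracted UD values; standardized set to NaN")
    z <- rep(NaN, length(raw))
  } else z <- (raw - mean(raw)) / s
  data.frame(raw = raw, standardized = z)
}

#' Write a UD grid as an ESRI ASCII raster
#'
#' @param grid a `ud_grid`.
#' @param path output file.
#' @export
write_ud_ascii <- function(grid, path) {
  nr <- length(grid$y); nc <- length(grid$x)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.6f", grid$x[1] - grid$cell_size / 2),
           sprintf("yllcorner %.6f", grid$y[1] - grid$cell_size / 2),
           sprintf("cellsize %.6f", grid$cell_size),
           "NODATA_value -9999")
  # ASCII rasters run north to south: top row = max y
  rows <- vapply(rev(seq_len(nr)), function(iy)
    paste(format(grid$values[, iy], digits = 10), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
}
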