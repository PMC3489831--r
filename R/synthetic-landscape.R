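#' Vegetation class scheme for the synthetic landscape
#'
#' Nine tundra vegetation classes with their approximate areal proportions
#' across the study region (fractions of mapped area). Sedge-grass meadow is
#' the reference class in all selection models.
#'
#' @return named numeric vector of proportions summing to 1.
#' @export
default_class_proportions <- function() {
  c(
    flooded            = 0.07,
    carex_aquatilis    = 0.02,
    riverine           = 0.05,
    wet_tundra         = 0.05,
    sedge_grass_meadow = 0.06,
    tussock_tundra     = 0.27,
    moss_lichen        = 0.01,
    dwarf_shrub        = 0.43,
    low_shrub          = 0.04
  )
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the data-generating process: grid geometry, the
#' vegetation class mixture and its spatial autocorrelation range, movement
#' parameters (gamma step lengths, von Mises turning angles), the true
#' selection coefficients used by the step-selection simulator, random
#' intercept standard deviations for animals and years, and the rates at
#' which low-quality fix records (2D fixes, high PDOP) are injected.
#'
#' @param grid_nrows,grid_ncols grid dimensions in cells.
#' @param cell_size cell edge (m).
#' @param class_proportions non-negative vector over the 9 vegetation
#'   classes, summing to 1.
#' @param spatial_range autocorrelation length of the landscape fields (m).
#' @param n_animals number of simulated animals.
#' @param n_steps_per_animal steps (relocations) per animal.
#' @param fix_interval hours between fixes (2 or 3).
#' @param step_scale mean step length (m).
#' @param turn_concentration von Mises concentration of turning angles.
#' @param true_beta named vector of selection coefficients; names must be
#'   vegetation class names or continuous layer names (`elev`, `dist_coast`).
#' @param re_sd_animal,re_sd_year standard deviations of animal and year
#'   random intercepts.
#' @param p_2d,p_highpdop injection rates for 2D-fix and PDOP>10 records.
#' @param lake_fraction fraction of inland cells covered by lakes.
#' @param relief total elevation range of the DEM (m).
#' @param n_candidates candidate endpoints per simulated step.
#' @param seed integer seed consumed by the generators.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_nrows = 200, grid_ncols = 200,
                             cell_size = 30,
                             class_proportions = default_class_proportions(),
                             spatial_range = 600,
                             n_animals = 10, n_steps_per_animal = 400,
                             fix_interval = 2,
                             step_scale = 400, turn_concentration = 1,
                             true_beta = c(sedge_grass_meadow = 1.0,
                                           flooded = -0.5, elev = 0.3),
                             re_sd_animal = 0.5, re_sd_year = 0.25,
                             p_2d = 0.015, p_highpdop = 0.011,
                             lake_fraction = 0.08, relief = 60,
                             n_candidates = 30, seed = 1L) {
  stopifnot(
    grid_nrows >= 1, grid_ncols >= 1, cell_size > 0,
    all(class_proportions >= 0),
    abs(sum(class_proportions) - 1) <= 1e-9,
    n_animals >= 1, n_steps_per_animal >= 1,
    fix_interval > 0, step_scale > 0, turn_concentration >= 0,
    re_sd_animal >= 0, re_sd_year >= 0,
    p_2d >= 0, p_highpdop >= 0, p_2d + p_highpdop < 1,
    lake_fraction >= 0, lake_fraction < 1, n_candidates >= 1
  )
  if (is.null(names(class_proportions))) {
    names(class_proportions) <- names(default_class_proportions())
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Stationary Gaussian random field on a grid
#'
#' White noise smoothed with an isotropic Gaussian kernel by FFT (circular
#' convolution on the torus), then standardized to mean 0 / sd 1. Draws from
#' the session RNG stream, so it is reproducible under `set.seed()`.
#'
#' @param nr,nc grid dimensions.
#' @param range_cells kernel length scale in cells; 0 gives white noise.
#' @return numeric matrix.
#' @export
gaussian_field <- function(nr, nc, range_cells) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return((w - mean(w)) / stats::sd(w))
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  d2 <- outer(di^2, dj^2, "+")
  k <- exp(-d2 / (2 * range_cells^2))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

rescale01 <- function(m) {
  r <- range(m, finite = TRUE)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Generate a synthetic landscape stack
#'
#' Builds a co-registered set of environmental layers with the statistical
#' character the selection analysis assumes: a spatially clumped categorical
#' vegetation mosaic hitting target class proportions (a Gaussian random
#' field cut at class quantiles), a smooth DEM, a sea margin along the
#' northern edge plus inland lakes (the water mask), a 10-day NDVI composite
#' stack whose phenology varies spatially, and a smooth precipitation layer.
#' Water cells carry no vegetation signal and NDVI below the no-growth
#' background.
#'
#' @param config a [synthetic_config()].
#' @return object of class `landscape_stack`: named `layers` (raster_grid:
#'   `veg_class`, `water`, `coast`, `dem`, `dist_coast`, `precip`), an
#'   `ndvi` element (`dates` day-of-year, `grids` list), `class_names`, and
#'   `cell_size`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nr <- config$grid_nrows; nc <- config$grid_ncols; cs <- config$cell_size
  p <- config$class_proportions
  ncell <- nr * nc
  pos <- p[p > 0]
  if (any(pos * ncell < 1)) {
    stop("degenerate input: grid too small to realize the smallest class proportion")
  }
  range_cells <- config$spatial_range / cs

  # vegetation mosaic: GRF cut at empirical quantiles -> exact counts
  f_veg <- gaussian_field(nr, nc, range_cells)
  counts <- diff(c(0, round(cumsum(p) * ncell)))
  counts[length(counts)] <- ncell - sum(counts[-length(counts)])
  cls <- integer(ncell)
  cls[order(as.vector(f_veg), stats::runif(ncell))] <-
    rep(seq_along(p), times = counts)
  veg <- matrix(cls, nr, nc)

  # DEM: smooth relief rising inland (southward) from the coast
  f_dem <- gaussian_field(nr, nc, range_cells * 2)
  inland <- matrix(seq_len(nr) / nr, nr, nc)
  dem <- config$relief * rescale01(0.7 * rescale01(f_dem) + 0.3 * inland)

  # water: sea strip along the north edge + inland lakes
  water <- matrix(FALSE, nr, nc)
  sea_rows <- max(1L, round(nr * 0.02))
  water[seq_len(sea_rows), ] <- TRUE
  if (config$lake_fraction > 0) {
    f_lake <- gaussian_field(nr, nc, range_cells / 2)
    inland_cells <- which(!water)
    thr <- stats::quantile(f_lake[inland_cells], config$lake_fraction)
    lakes <- f_lake <= thr & !water
    water <- water | lakes
  }
  coast <- matrix(FALSE, nr, nc)
  coast[sea_rows, ] <- TRUE  # seaward boundary row

  # NDVI 10-day composites generated at coarse native resolution, then
  # nearest-neighbour resampled to the analysis grid
  fac <- max(1L, min(4L, nr %/% 8L, nc %/% 8L))
  cnr <- ceiling(nr / fac); cnc <- ceiling(nc / fac)
  peak <- 185 + 30 * rescale01(gaussian_field(cnr, cnc, range_cells / fac))
  amp <- 0.45 + 0.3 * rescale01(gaussian_field(cnr, cnc, range_cells / fac))
  dates <- seq(150, 280, by = 10)
  up <- function(m) m[rep(seq_len(cnr), each = fac)[seq_len(nr)],
                      rep(seq_len(cnc), each = fac)[seq_len(nc)], drop = FALSE]
  peak_f <- up(peak); amp_f <- up(amp)
  ndvi_grids <- lapply(dates, function(d) {
    v <- 0.02 + amp_f * exp(-0.5 * ((d - peak_f) / 25)^2)
    v[water] <- 0.02
    raster_grid(v, cellsize = cs)
  })

  precip <- 10 + 50 * rescale01(gaussian_field(nr, nc, range_cells * 2))

  stack <- structure(
    list(
      layers = list(
        veg_class = raster_grid(veg, cellsize = cs),
        water = raster_grid(water + 0, cellsize = cs),
        coast = raster_grid(coast + 0, cellsize = cs),
        dem = raster_grid(dem, cellsize = cs),
        precip = raster_grid(precip, cellsize = cs)
      ),
      ndvi = list(dates = dates, grids = ndvi_grids),
      class_names = names(p),
      cell_size = cs
    ),
    class = "landscape_stack"
  )
  stack$layers$dist_coast <- distance_to_coast(stack$layers$coast)
  stack
}

#' @export
print.landscape_stack <- function(x, ...) {
  d <- dim(x$layers$veg_class$values)
  cat(sprintf("<landscape_stack> %d x %d cells @ %g m\n", d[1], d[2],
              x$cell_size))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  ndvi: %d composites (doy %d..%d)\n",
              length(x$ndvi$dates), min(x$ndvi$dates), max(x$ndvi$dates)))
  invisible(x)
}

#' Logical land mask (non-water cells) of a landscape stack
#' @param stack a `landscape_stack`.
#' @return logical matrix, `TRUE` on land.
#' @export
land_mask <- function(stack) stack$layers$water$values == 0
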