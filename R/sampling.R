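#' Kernel-density range polygon (95% isopleth)
#'
#' Estimates a Gaussian product-kernel density of the fixes on a regular
#' grid, with the ad hoc (normal reference) bandwidth
#' `h_j = sd_j * n^(-1/6)` per axis, and returns the smallest-density
#' contour enclosing at least `level` of the total density mass. The range
#' is carried both as a cell mask (used for fast point containment and
#' availability sampling) and as contour polygons.
#'
#' @param points data.frame with `x`, `y` (>= 30 rows).
#' @param level isopleth probability mass (default 0.95).
#' @param cellsize evaluation grid resolution (m); defaults to a 128x128
#'   grid over the padded point extent.
#' @param bandwidth optional per-axis bandwidth override (length 2, m).
#' @return object of class `range_polygon`: `mask` (raster_grid, 1 inside),
#'   `density` (raster_grid), `polygons` (list of x/y lists), `level`,
#'   `bandwidth`, `threshold`.
#' @export
kde_range <- function(points, level = 0.95, cellsize = NULL,
                      bandwidth = NULL) {
  x <- points$x; y <- points$y
  n <- length(x)
  stopifnot(n >= 30)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("degenerate point set: all points identical")
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  }
  bandwidth[bandwidth <= 0] <- max(bandwidth) # guard a degenerate axis
  pad <- 3 * bandwidth
  xr <- range(x) + c(-1, 1) * pad[1]
  yr <- range(y) + c(-1, 1) * pad[2]
  if (is.null(cellsize)) cellsize <- max(diff(xr), diff(yr)) / 128
  gx <- seq(xr[1] + cellsize / 2, xr[2], by = cellsize)
  gy <- seq(yr[1] + cellsize / 2, yr[2], by = cellsize)
  zx <- stats::dnorm(outer(gx, x, "-") / bandwidth[1]) / bandwidth[1]
  zy <- stats::dnorm(outer(gy, y, "-") / bandwidth[2]) / bandwidth[2]
  dens_xy <- zx %*% t(zy) / n                  # [x, y] orientation
  mass <- dens_xy / sum(dens_xy)
  o <- order(dens_xy, decreasing = TRUE)
  cum <- cumsum(mass[o])
  if (level >= 1) {
    threshold <- 0                 # the full evaluated support
  } else {
    k <- which(cum >= level)[1]
    if (is.na(k)) k <- length(o)
    threshold <- dens_xy[o[k]]
  }
  inside <- dens_xy >= threshold
  # to raster orientation: rows north->south
  to_grid <- function(m_xy) {
    raster_grid(t(m_xy)[rev(seq_along(gy)), , drop = FALSE],
                xmin = gx[1] - cellsize / 2, ymin = gy[1] - cellsize / 2,
                cellsize = cellsize)
  }
  cl <- grDevices::contourLines(gx, gy, dens_xy, levels = threshold)
  structure(
    list(mask = to_grid(inside + 0), density = to_grid(dens_xy),
         polygons = cl, level = level, bandwidth = bandwidth,
         threshold = threshold),
    class = "range_polygon"
  )
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf(
    "<range_polygon> %g%% isopleth, bandwidth (%.1f, %.1f) m, %d polygon(s)\n",
    100 * x$level, x$bandwidth[1], x$bandwidth[2], length(x$polygons)))
  invisible(x)
}

#' Test whether points fall inside a range polygon
#'
#' Containment is evaluated on the isopleth cell mask.
#'
#' @param range a [kde_range()] result.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
in_range <- function(range, x, y) {
  v <- rg_extract(range$mask, x, y)
  !is.na(v) & v == 1
}

#' Uniform availability sample within a seasonal range
#'
#' Draws `n` points uniformly over the intersection of the range isopleth
#' and (optionally) non-water land, by rejection sampling from the range's
#' bounding box.
#'
#' @param range a [kde_range()] result.
#' @param n number of points (>= 1).
#' @param stack optional `landscape_stack`; when supplied, points on water
#'   or outside the raster are rejected.
#' @param seed integer seed.
#' @param screen_water reject points on water (default TRUE).
#' @return data.frame `x`, `y`.
#' @export
sample_available_landscape <- function(range, n, stack = NULL, seed = 1L,
                                       screen_water = TRUE) {
  stopifnot(n >= 1)
  set.seed(seed)
  m <- range$mask
  xr <- c(m$xmin, rg_xmax(m)); yr <- c(m$ymin, rg_ymax(m))
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(1000L)) {
    need <- n - length(xs)
    if (need <= 0) break
    cx <- stats::runif(2 * need + 100, xr[1], xr[2])
    cy <- stats::runif(2 * need + 100, yr[1], yr[2])
    ok <- in_range(range, cx, cy)
    if (!is.null(stack) && screen_water) {
      w <- rg_extract(stack$layers$water, cx, cy)
      ok <- ok & !is.na(w) & w == 0
    }
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  if (length(xs) < n) stop("availability sampling failed: range may be entirely water")
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Matched step-based availability sample (patch scale)
#'
#' For every used fix after the first in an animal-season, draws
#' `n_per_used` available endpoints by resampling (with replacement)
#' movement rates and absolute bearings from the empirical set of all
#' sequential moves of that animal in that season, displacing the previous
#' fix by `rate * dt` along the bearing. Pairs landing off the raster or on
#' water are redrawn up to 100 times; a stratum whose candidates never land
#' is dropped with a log entry. Each used fix and its matches share a
#' unique stratum id.
#'
#' @param track fix data.frame with `animal_id`, `season`, `timestamp`,
#'   `x`, `y` (plus metadata carried onto strata rows).
#' @param n_per_used available points per used fix (default 5).
#' @param stack optional `landscape_stack` for water/extent screening.
#' @param seed integer seed.
#' @return a used-available data.frame: columns of `track` metadata plus
#'   `x`, `y`, `used` (0/1), `stratum`; attribute `n_dropped_strata`.
#' @export
sample_available_steps <- function(track, n_per_used = 5, stack = NULL,
                                   seed = 1L) {
  set.seed(seed)
  if (!"season" %in% names(track)) track$season <- "all"
  meta_cols <- intersect(c("animal_id", "year", "season", "parturient",
                           "insect_state", "timestamp"), names(track))
  valid_pt <- function(x, y) {
    if (is.null(stack)) return(rep(TRUE, length(x)))
    w <- rg_extract(stack$layers$water, x, y)
    !is.na(w) & w == 0
  }
  res <- list(); dropped <- 0L; stratum <- 0L
  key <- paste(track$animal_id, track$season)
  for (k in unique(key)) {
    d <- track[key == k, , drop = FALSE]
    d <- d[order(d$timestamp), , drop = FALSE]
    if (nrow(d) < 2) next
    dt <- as.numeric(diff(d$timestamp), units = "hours")
    dx <- diff(d$x); dy <- diff(d$y)
    rates <- sqrt(dx^2 + dy^2) / dt
    brgs <- atan2(dx, dy)
    for (i in 2:nrow(d)) {
      stratum <- stratum + 1L
      px <- d$x[i - 1]; py <- d$y[i - 1]; dti <- dt[i - 1]
      ax <- numeric(0); ay <- numeric(0)
      for (try in seq_len(100L)) {
        need <- n_per_used - length(ax)
        if (need <= 0) break
        j <- sample.int(length(rates), need, replace = TRUE)
        cx <- px + rates[j] * dti * sin(brgs[j])
        cy <- py + rates[j] * dti * cos(brgs[j])
        ok <- valid_pt(cx, cy)
        ax <- c(ax, cx[ok]); ay <- c(ay, cy[ok])
      }
      if (length(ax) < n_per_used) { dropped <- dropped + 1L; next }
      meta <- d[rep(i, n_per_used + 1), meta_cols, drop = FALSE]
      meta$x <- c(d$x[i], ax[seq_len(n_per_used)])
      meta$y <- c(d$y[i], ay[seq_len(n_per_used)])
      meta$used <- c(1L, rep(0L, n_per_used))
      meta$stratum <- stratum
      res[[length(res) + 1]] <- meta
    }
  }
  if (length(res) == 0) {
    stop("no animal-season had >= 2 fixes; cannot build step availability")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_dropped_strata") <- dropped
  out
}
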