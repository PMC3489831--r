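# shared small fixtures, built in code at test time

# a fix table whose consecutive displacements (m) are given; first fix at
# (0, 0), moves due east
toy_track <- function(displacements, animal = "A01",
                      t0 = as.POSIXct("2006-06-20 00:00:00", tz = "UTC")) {
  x <- cumsum(c(0, displacements))
  data.frame(
    animal_id = animal,
    timestamp = t0 + seq_along(x) * 7200,
    x = x, y = 0,
    fix_dim = "3D", pdop = 2
  )
}

# small landscape used across covariate/sampling tests (cached per session)
tiny_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(grid_nrows = 80, grid_ncols = 80,
                              spatial_range = 300, seed = 42)
      cache <<- generate_landscape(cfg)
    }
    cache
  }
})

# minimal hand-built stack with controlled layer values; 6x6 grid, 30 m
# cells, water in the north-west corner cell, coast along row 1
hand_stack <- function() {
  nr <- 6; nc <- 6
  veg <- matrix(5, nr, nc)           # sedge_grass_meadow everywhere...
  veg[4, ] <- 1                      # ...except a flooded band
  water <- matrix(0, nr, nc); water[1, 1] <- 1
  coast <- matrix(0, nr, nc); coast[1, ] <- 1
  dem <- matrix(10, nr, nc)
  precip <- matrix(20, nr, nc)
  mk <- function(v) raster_grid(v, cellsize = 30)
  st <- structure(list(
    layers = list(veg_class = mk(veg), water = mk(water), coast = mk(coast),
                  dem = mk(dem), precip = mk(precip)),
    ndvi = list(dates = c(160, 180, 200, 220),
                grids = list(mk(matrix(0.05, nr, nc)),
                             mk(matrix(0.3, nr, nc)),
                             mk(matrix(0.5, nr, nc)),
                             mk(matrix(0.05, nr, nc)))),
    class_names = names(default_class_proportions()),
    cell_size = 30
  ), class = "landscape_stack")
  st$layers$dist_coast <- distance_to_coast(st$layers$coast)
  st
}
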