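test_that("TTLQV matches the nested-loop oracle on stripe rasters", {
  # the V3 curve of an equal square wave peaks just below the stripe
  # width (continuous optimum ~15/16 of the width); the frozen values
  # below are what the brute-force oracle yields
  expected_bstar <- c(`4` = 4L, `8` = 7L, `16` = 15L)
  for (w in c(4, 8, 16)) {
    v <- matrix(rep(rep(c(1, 2), each = w), length.out = 96),
                48, 96, byrow = TRUE)
    g <- raster_grid(v)
    res <- ttlqv_scale(g, 1, max_block = 16)
    expect_equal(res$b_star, oracle_ttlqv_bstar(v == 1, 16))
    expect_equal(res$b_star, expected_bstar[[as.character(w)]])
    expect_equal(res$scale_m, res$b_star * 30)
  }
})

test_that("TTLQV is transpose-invariant and rejects degenerate indicators", {
  set.seed(11)
  v <- matrix(sample(1:2, 40 * 40, replace = TRUE, prob = c(0.3, 0.7)),
              40, 40)
  g <- raster_grid(v)
  gt <- raster_grid(t(v))
  expect_equal(ttlqv_scale(g, 1, 12)$b_star, ttlqv_scale(gt, 1, 12)$b_star)
  expect_error(ttlqv_scale(g, 5, 12), "absent")
  expect_error(ttlqv_scale(raster_grid(matrix(1, 20, 20)), 1, 6),
               "degenerate")
})

test_that("moving-window density equals brute-force counting", {
  set.seed(12)
  v <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
  v[3, 5] <- NA
  g <- raster_grid(v)
  got <- moving_window_density(g, 2, window_m = 5 * 30)
  expect_equal(got$values, oracle_density(v, 2, 5), tolerance = 1e-12)
  expect_true(all(got$values >= 0 & got$values <= 1, na.rm = TRUE))

  # all-class-k raster -> density 1; single cell, 3x3 window -> centre 1/9
  allk <- raster_grid(matrix(2, 10, 10))
  expect_true(all(moving_window_density(allk, 2, 90)$values == 1))
  single <- matrix(1, 9, 9); single[5, 5] <- 2
  d1 <- moving_window_density(raster_grid(single), 2, 90)
  expect_equal(d1$values[5, 5], 1 / 9)

  # window covering the full raster reproduces the global proportion
  dall <- moving_window_density(g, 2, 30 * 2 * 20 + 30)
  expect_equal(dall$values[1, 1], mean(v == 2, na.rm = TRUE))
})

test_that("VRM is zero on planes and matches the vector-sum oracle", {
  flat <- raster_grid(matrix(7, 15, 15))
  expect_true(all(vrm(flat)$values == 0))
  incl <- raster_grid(outer(1:15, 1:15, function(i, j) 3 * i - 2 * j))
  expect_lt(max(vrm(incl)$values), 1e-12)

  set.seed(13)
  z <- matrix(rnorm(225, 0, 15), 15, 15)
  rough <- raster_grid(z)
  got <- vrm(rough, window = 8)
  expect_equal(got$values, oracle_vrm(z, 30, 8), tolerance = 1e-10)
  expect_true(all(got$values >= 0 & got$values <= 1))
  # invariant to a constant elevation shift
  expect_equal(vrm(raster_grid(z + 500), 8)$values, got$values,
               tolerance = 1e-12)
})

test_that("NDVI phenology dates follow the 0.1 threshold rules", {
  mk <- function(vals) {
    list(dates = seq(150, by = 10, length.out = length(vals)),
         grids = lapply(vals, function(v) raster_grid(matrix(v, 2, 2))))
  }
  ph <- ndvi_phenology(mk(c(0.05, 0.2, 0.6, 0.3, 0.08)))
  expect_equal(ph$greenup_date$values[1, 1], 160)
  expect_equal(ph$maxgrowth_date$values[1, 1], 170)
  expect_equal(ph$senescence_date$values[1, 1], 190)

  ph0 <- ndvi_phenology(mk(rep(0.05, 5)))
  expect_true(all(is.na(ph0$greenup_date$values)))
  expect_true(all(is.na(ph0$maxgrowth_date$values)))

  tie <- ndvi_phenology(mk(c(0.05, 0.6, 0.6, 0.05)))
  expect_equal(tie$maxgrowth_date$values[1, 1], 160)  # earlier date on tie

  # ordering invariant on a generated landscape
  st <- tiny_stack()
  ph2 <- ndvi_phenology(st$ndvi)
  ok <- !is.na(ph2$senescence_date$values)
  expect_true(all(ph2$greenup_date$values[ok] <=
                    ph2$maxgrowth_date$values[ok]))
  expect_true(all(ph2$maxgrowth_date$values[ok] <=
                    ph2$senescence_date$values[ok]))
})

test_that("distance to coast is exact against all-pairs brute force", {
  m <- matrix(0, 12, 12); m[1, 4] <- 1
  g <- raster_grid(m)
  d <- distance_to_coast(g)
  expect_equal(d$values[1, 4], 0)
  expect_equal(d$values[1, 12], 8 * 30)   # 8 cells due east of the coast cell
  set.seed(14)
  m2 <- matrix(rbinom(900, 1, 0.05), 30, 30)
  if (sum(m2) == 0) m2[7, 9] <- 1
  d2 <- distance_to_coast(raster_grid(m2))
  expect_equal(d2$values, oracle_dist_coast(m2, 30), tolerance = 1e-9)
  expect_error(distance_to_coast(raster_grid(matrix(0, 4, 4))), "empty")
})

test_that("design tables standardize, guard transforms, omit the reference", {
  st <- hand_stack()
  co <- rg_coords(st$layers$veg_class)
  land <- land_mask(st)
  pts <- data.frame(x = co$x[land], y = co$y[land],
                    used = rep_len(c(1, 0), sum(land)))
  ct <- build_design(pts, st,
                     covariates = c("veg_patch", "elev", "dist_coast"),
                     squared = "dist_coast")
  cols <- attr(ct, "covariate_cols")
  expect_equal(sum(startsWith(cols, "patch_")), 8)
  expect_false("patch_sedge_grass_meadow" %in% cols)
  # sedge-grass rows have all-zero dummies
  sedge_rows <- rowSums(ct[, grep("^patch_", cols, value = TRUE)]) == 0
  veg_at <- rg_extract(st$layers$veg_class, ct$x, ct$y)
  expect_equal(unname(sedge_rows), veg_at == 5)
  # standardized columns: mean 0, sd 1
  expect_lt(abs(mean(ct$dist_coast)), 1e-8)
  expect_equal(stats::sd(ct$dist_coast), 1, tolerance = 1e-8)
  # zero-guard: a coast-adjacent water-free cell at distance 0 would map to
  # log(cellsize); reconstruct raw transformed values from the scaling
  sc <- attr(ct, "scaling")$dist_coast
  raw <- ct$dist_coast * sc["sd"] + sc["mean"]
  d0 <- rg_extract(st$layers$dist_coast, ct$x, ct$y)
  expect_equal(unname(raw), log(d0 + 30), tolerance = 1e-10)
  # squared term is the square of the standardized column
  expect_equal(ct$dist_coast_sq, ct$dist_coast^2)
  # water points are dropped with a count
  wet <- rbind(pts, data.frame(x = 15, y = co$y[1, 1], used = 0))
  ct2 <- build_design(wet, st, covariates = c("veg_patch", "elev"))
  expect_equal(attr(ct2, "n_dropped_nodata"), 1)
})

test_that("VIF pruning matches an independent lm-based recomputation", {
  set.seed(15)
  n <- 300
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # orthogonal-ish columns: nothing pruned
  res <- vif_prune(X, 3)
  expect_equal(res$dropped, character(0))
  expect_true(all(res$vif < 1.1))

  # duplicated column: one copy dropped
  X2 <- X; X2$a2 <- X2$a
  res2 <- vif_prune(X2, 3)
  expect_length(res2$dropped, 1)
  expect_true(res2$dropped %in% c("a", "a2"))

  # near-linear combination: survivors match the lm-based oracle
  X3 <- X
  X3$d <- 0.7 * X3$a + 0.7 * X3$b + rnorm(n, 0, 0.15)
  res3 <- vif_prune(X3, 3)
  expect_setequal(res3$retained, oracle_vif_prune(X3, 3))
  expect_true(all(res3$vif <= 3))
  # termination in at most ncol-1 drops
  expect_lte(length(res3$dropped), ncol(X3) - 1)
})
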