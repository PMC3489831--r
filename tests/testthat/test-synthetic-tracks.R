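test_that("seeded track simulation is bit-reproducible", {
  st <- tiny_stack()
  cfg <- synthetic_config(grid_nrows = 80, grid_ncols = 80,
                          spatial_range = 300, n_animals = 3,
                          n_steps_per_animal = 50, seed = 42)
  a <- simulate_tracks(st, cfg)
  b <- simulate_tracks(st, cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
})

test_that("tracks stay on the raster, bearings are wrapped, fixes stamped", {
  st <- tiny_stack()
  cfg <- synthetic_config(grid_nrows = 80, grid_ncols = 80,
                          spatial_range = 300, n_animals = 2,
                          n_steps_per_animal = 60, fix_interval = 3,
                          seed = 9)
  sim <- simulate_tracks(st, cfg)
  g <- st$layers$veg_class
  expect_true(all(sim$tracks$x >= g$xmin & sim$tracks$x < rg_xmax(g)))
  expect_true(all(sim$tracks$y >= g$ymin & sim$tracks$y < rg_ymax(g)))
  expect_true(all(sim$truth$realized_bearings >= -pi &
                    sim$truth$realized_bearings < pi))
  dt <- diff(sim$tracks$timestamp[sim$tracks$animal_id == "A01"])
  expect_true(all(as.numeric(dt, units = "hours") == 3))
  expect_length(sim$truth$per_animal_intercepts, 2)
})

test_that("neutral selection uses candidates in proportion to availability", {
  st <- tiny_stack()
  cfg <- synthetic_config(grid_nrows = 80, grid_ncols = 80,
                          spatial_range = 300, n_animals = 10,
                          n_steps_per_animal = 1000,
                          true_beta = c(sedge_grass_meadow = 0),
                          p_2d = 0, p_highpdop = 0, seed = 21)
  sim <- simulate_tracks(st, cfg)
  used_cls <- rg_extract(st$layers$veg_class,
                         sim$tracks$x, sim$tracks$y)
  used_cls <- used_cls[!is.na(used_cls)]
  obs <- tabulate(used_cls, 9)
  p_cand <- sim$truth$candidate_class_counts /
    sum(sim$truth$candidate_class_counts)
  keep <- p_cand > 0
  ct <- suppressWarnings(
    stats::chisq.test(obs[keep], p = p_cand[keep] / sum(p_cand[keep])))
  expect_gt(ct$p.value, 0.01)
})

test_that("strong selection concentrates use as the softmax model predicts", {
  p <- c(0.10, 0.10, 0.10, 0.10, 0.10, 0.20, 0.10, 0.10, 0.10)
  names(p) <- names(default_class_proportions())
  cfg <- synthetic_config(grid_nrows = 100, grid_ncols = 100,
                          class_proportions = p, spatial_range = 150,
                          n_animals = 6, n_steps_per_animal = 500,
                          true_beta = c(flooded = 3),
                          p_2d = 0, p_highpdop = 0, lake_fraction = 0,
                          seed = 22)
  st <- generate_landscape(cfg)
  sim <- simulate_tracks(st, cfg)
  used_cls <- rg_extract(st$layers$veg_class, sim$tracks$x, sim$tracks$y)
  frac_A <- mean(used_cls == 1, na.rm = TRUE)
  # independent oracle: with candidates ~ Bin(K, p_A), the softmax pick
  # lands in A with probability E[ n e^3 / (n e^3 + K - n) ]
  p_A <- sim$truth$candidate_class_counts[["flooded"]] /
    sum(sim$truth$candidate_class_counts)
  K <- cfg$n_candidates
  n <- 0:K
  expected <- sum(stats::dbinom(n, K, p_A) *
                    ifelse(n == 0, 0, n * exp(3) / (n * exp(3) + K - n)))
  expect_gt(frac_A, 0.6)                   # strong enrichment over ~10%
  expect_lt(abs(frac_A - expected), 0.08)  # matches the selection model
})

test_that("injected 2D/PDOP noise rates match configuration within 1 point", {
  st <- tiny_stack()
  cfg <- synthetic_config(grid_nrows = 80, grid_ncols = 80,
                          spatial_range = 300, n_animals = 20,
                          n_steps_per_animal = 500,
                          p_2d = 0.015, p_highpdop = 0.011, seed = 23)
  sim <- simulate_tracks(st, cfg)
  n <- nrow(sim$tracks)
  expect_gte(n, 10000)
  expect_lt(abs(mean(sim$tracks$fix_dim == "2D") - 0.015), 0.01)
  expect_lt(abs(mean(sim$tracks$pdop > 10) - 0.011), 0.01)
})

test_that("von Mises sampler concentrates around the mean direction", {
  set.seed(1)
  th <- rvonmises(20000, 0.5, kappa = 4)
  expect_true(all(th >= -pi & th < pi))
  # circular mean and resultant length vs the theoretical A(kappa)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  mu_hat <- atan2(mean(sin(th)), mean(cos(th)))
  A4 <- besselI(4, 1) / besselI(4, 0)
  expect_lt(abs(mu_hat - 0.5), 0.05)
  expect_lt(abs(R - A4), 0.02)
  expect_true(all(abs(rvonmises(100, 0, 0)) <= pi))
})
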