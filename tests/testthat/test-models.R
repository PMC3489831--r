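test_that("zero random-effect variance reduces the GLMM to plain logistic", {
  d <- simulate_glmm_data(n_animals = 30, n_per_animal = 40,
                          beta = c(1, -0.5), sd_animal = 0, sd_year = 0,
                          seed = 81)
  mf <- suppressMessages(fit_mixed_logistic(d))
  gf <- stats::glm(used ~ x1 + x2, data = d, family = stats::binomial())
  expect_lt(max(abs(mf$beta - stats::coef(gf)[-1])), 1e-3)
  expect_lt(abs(mf$intercept - stats::coef(gf)[1]), 1e-3)
})

test_that("GLMM recovers coefficients and intercept spread (small check)", {
  d <- simulate_glmm_data(n_animals = 50, n_per_animal = 40,
                          beta = c(1, -0.5), sd_animal = 1, seed = 82)
  mf <- suppressMessages(fit_mixed_logistic(d))
  expect_lt(abs(mf$beta[["x1"]] - 1), 0.3)
  expect_lt(abs(mf$beta[["x2"]] + 0.5), 0.3)
  expect_lt(abs(mf$re_sd[["animal_id"]] - 1), 0.4)
  expect_equal(mf$aic, -2 * mf$loglik + 2 * mf$k, tolerance = 1e-10)
})

test_that("all-subsets AIC fits every combination, order-invariantly", {
  d <- simulate_clogit_data(n_animals = 3, n_steps = 100,
                            beta = c(1.2, 0, 0), seed = 83)
  blocks <- list(b1 = "x1", b2 = "x2", b3 = "x3", b4 = c("x2", "x3"))
  sel <- suppressWarnings(all_subsets_aic(d, blocks))
  expect_equal(nrow(sel$ranking) + length(sel$failed), 15)  # 2^4 - 1
  perm <- suppressWarnings(all_subsets_aic(d, blocks[c(3, 1, 4, 2)]))
  expect_setequal(sel$best_blocks, perm$best_blocks)
  expect_equal(sel$best_fit$aic, perm$best_fit$aic)
  expect_true("b1" %in% sel$best_blocks)
})

test_that("AIC selection prefers the generating block most of the time", {
  # AIC admits a spurious extra block with probability ~ P(chisq_1 > 2),
  # so with two null blocks the exact generating model wins only ~60% of
  # finite-sample replicates; the generating block itself must always be
  # retained
  wins <- 0; kept <- 0
  for (s in 1:20) {
    d <- simulate_clogit_data(n_animals = 2, n_steps = 150,
                              beta = c(1.2, 0, 0), seed = 90 + s)
    sel <- all_subsets_aic(d, list(veg = "x1", elev = "x2", rug = "x3"))
    if (identical(sel$best_blocks, "veg")) wins <- wins + 1
    if ("veg" %in% sel$best_blocks) kept <- kept + 1
  }
  expect_equal(kept, 20)
  expect_gte(wins, 7)
})

test_that("quadratic screening adds squares only for curved responses", {
  set.seed(101)
  lin_adds <- 0; curve_adds <- 0; neg_sign <- TRUE
  for (s in 1:10) {
    n <- 800
    x <- rnorm(n)
    lin <- data.frame(used = rbinom(n, 1, plogis(0.8 * x)), x = x)
    if (length(quadratic_screen(lin, "x")$squared) > 0) {
      lin_adds <- lin_adds + 1
    }
    crv <- data.frame(used = rbinom(n, 1, plogis(1 - 1.2 * x^2)), x = x)
    qc <- quadratic_screen(crv, "x")
    if (length(qc$squared) > 0) {
      curve_adds <- curve_adds + 1
      neg_sign <- neg_sign && qc$log$quad_sign[1] < 0
    }
  }
  expect_lte(lin_adds, 1)           # false positives are rare
  expect_gte(curve_adds, 9)         # curvature is detected
  expect_true(neg_sign)             # concave response -> negative square
  cst <- data.frame(used = rbinom(50, 1, 0.5), x = rep(1, 50))
  expect_length(quadratic_screen(cst, "x")$squared, 0)
})

test_that("residual lag is 1 for independent data, > 1 under persistence", {
  iid_lag_one <- 0
  for (s in 1:5) {
    d <- simulate_clogit_data(n_animals = 3, n_steps = 120,
                              beta = c(1, -0.5), seed = 110 + s)
    fit <- fit_conditional_logistic(d, c("x1", "x2"))
    rl <- residual_lag(fit, d)
    if (rl$lag == 1) iid_lag_one <- iid_lag_one + 1
  }
  expect_gte(iid_lag_one, 4)

  # persistence: an omitted AR(1) term in a used-available time series
  # leaves autocorrelated deviance residuals that push the lag above 1
  ar_detected <- 0
  for (s in 1:5) {
    set.seed(130 + s)
    m <- 500
    mk <- function(a) {
      u <- as.numeric(stats::filter(rnorm(m, 0, 0.6), 0.9,
                                    method = "recursive"))
      x <- rnorm(m)
      data.frame(x1 = x, used = rbinom(m, 1, plogis(0.8 * x + u)),
                 animal_id = a,
                 timestamp = as.POSIXct("2006-06-01", tz = "UTC") +
                   seq_len(m) * 7200)
    }
    d <- rbind(mk("A01"), mk("A02"), mk("A03"))
    fit <- fit_mixed_logistic(d, "x1", re_factors = character(0))
    if (residual_lag(fit, d)$lag > 1) ar_detected <- ar_detected + 1
  }
  expect_gte(ar_detected, 4)
})

test_that("robust split-sample refit averages the two group covariances", {
  d <- simulate_clogit_data(n_animals = 4, n_steps = 150,
                            beta = c(1, -0.5), seed = 141)
  fit <- fit_conditional_logistic(d, c("x1", "x2"))
  rr <- robust_refit(fit, d, lag = 1)
  # independent data: robust SE should sit near naive * sqrt(2) (each
  # group has half the information)
  ratio <- rr$se_robust / rr$se_naive
  expect_true(all(abs(ratio - sqrt(2)) < 0.25 * sqrt(2)))
  expect_true(all(rr$se_robust > 0))
  expect_true(all(rr$significant))

  # two identical groups by construction -> vcov equals either group's
  d1 <- d
  d1$stratum <- d1$stratum + 1000000L      # distinct ids, same data
  dd <- rbind(d, d1)
  # interleave in time so alternating strata are exact copies
  dd <- dd[order(dd$animal_id, dd$timestamp, dd$stratum), ]
  fit_all <- fit_conditional_logistic(dd, c("x1", "x2"))
  rr2 <- robust_refit(fit_all, dd, lag = 1)
  f1 <- fit_conditional_logistic(d, c("x1", "x2"))
  expect_equal(unname(rr2$vcov_robust), unname(f1$vcov_naive),
               tolerance = 1e-8)
})

test_that("significance flags follow the 95% robust confidence interval", {
  d <- simulate_clogit_data(n_animals = 4, n_steps = 200,
                            beta = c(1.5, 0), seed = 142)
  fit <- fit_conditional_logistic(d, c("x1", "x2"))
  rr <- robust_refit(fit, d, lag = 1)
  expect_true(rr$significant[["x1"]])
  expect_false(rr$significant[["x2"]])
  expect_equal(unname(rr$significant),
               unname(abs(rr$beta) - 1.96 * rr$se_robust > 0))
})
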