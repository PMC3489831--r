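#' Simulate matched used-available strata from a known step-selection model
#'
#' Generates the conditional-logistic data-generating process directly:
#' every step contributes a stratum of `n_avail + 1` candidate endpoints
#' with independent standard-normal covariates, and the used endpoint is
#' drawn among them with probability proportional to `exp(beta' x)`. This
#' is the ground-truth generator for coefficient recovery and confidence
#' interval coverage checks of the patch-scale estimator.
#'
#' @param n_animals,n_steps simulated animals and steps per animal.
#' @param beta true coefficient vector (covariates are named `x1..xk`).
#' @param n_avail available rows per stratum (default 5, the 5:1 design).
#' @param seed integer seed.
#' @return data.frame `x1..xk`, `used`, `stratum`, `animal_id`,
#'   `timestamp`.
#' @export
simulate_clogit_data <- function(n_animals = 20, n_steps = 500,
                                 beta = c(1.0, -0.5, 0.3), n_avail = 5,
                                 seed = 1L) {
  set.seed(seed)
  k <- length(beta)
  J <- n_avail + 1
  n_str <- n_animals * n_steps
  X <- matrix(stats::rnorm(n_str * J * k), n_str * J, k)
  colnames(X) <- paste0("x", seq_len(k))
  stratum <- rep(seq_len(n_str), each = J)
  eta <- matrix(X %*% beta, ncol = J, byrow = TRUE)
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  pick <- vapply(seq_len(n_str), function(s) {
    sample.int(J, 1, prob = pr[s, ])
  }, integer(1))
  used <- integer(n_str * J)
  used[(seq_len(n_str) - 1) * J + pick] <- 1L
  animal <- rep(sprintf("A%02d", seq_len(n_animals)), each = n_steps * J)
  step_i <- rep(rep(seq_len(n_steps), each = J), times = n_animals)
  t0 <- as.POSIXct("2006-06-01 00:00:00", tz = "UTC")
  out <- data.frame(X, used = used, stratum = stratum,
                    animal_id = animal,
                    timestamp = t0 + step_i * 7200)
  attr(out, "covariate_cols") <- colnames(X)
  attr(out, "true_beta") <- beta
  out
}

#' Simulate used-available data from a known random-intercept logistic model
#'
#' Landscape-scale ground truth: each animal-year contributes rows whose
#' use probability is `plogis(b0 + beta' x + a_animal + a_year)` with
#' standard-normal covariates and normal random intercepts.
#'
#' @param n_animals animals (clusters).
#' @param n_per_animal rows per animal.
#' @param beta fixed-effect coefficients (covariates `x1..xk`).
#' @param intercept fixed intercept `b0`.
#' @param sd_animal,sd_year random-intercept standard deviations.
#' @param n_years synthetic years animals are spread over.
#' @param seed integer seed.
#' @return data.frame `x1..xk`, `used`, `animal_id`, `year`, `timestamp`;
#'   attribute `true_intercepts`.
#' @export
simulate_glmm_data <- function(n_animals = 50, n_per_animal = 40,
                               beta = c(1.0, -0.5), intercept = 0,
                               sd_animal = 1.0, sd_year = 0,
                               n_years = 2, seed = 1L) {
  set.seed(seed)
  k <- length(beta)
  n <- n_animals * n_per_animal
  X <- matrix(stats::rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  animal <- rep(sprintf("A%02d", seq_len(n_animals)), each = n_per_animal)
  years <- 2004L + (seq_len(n_animals) - 1L) %% n_years
  a_int <- stats::rnorm(n_animals, 0, sd_animal)
  y_int <- stats::rnorm(n_years, 0, sd_year)
  eta <- intercept + as.vector(X %*% beta) +
    rep(a_int, each = n_per_animal) +
    rep(y_int[(years - 2004L) + 1L], each = n_per_animal)
  used <- stats::rbinom(n, 1, stats::plogis(eta))
  t0 <- as.POSIXct("2006-06-01 00:00:00", tz = "UTC")
  out <- data.frame(X, used = used, animal_id = animal,
                    year = rep(years, each = n_per_animal),
                    timestamp = t0 + stats::ave(seq_len(n), animal,
                                                FUN = seq_along) * 7200)
  attr(out, "covariate_cols") <- colnames(X)
  attr(out, "true_intercepts") <- list(animal = a_int, year = y_int)
  out
}
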