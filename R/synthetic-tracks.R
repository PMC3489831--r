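#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles wrapped to `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)) + mu
    take <- th[seq_len(min(length(th), m))]
    out[filled + seq_along(take)] <- take
    filled <- filled + length(take)
  }
  wrap_angle(out)
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

reflect_into <- function(x, lo, hi) {
  l <- hi - lo
  y <- (x - lo) %% (2 * l)
  y <- ifelse(y > l, 2 * l - y, y)
  lo + y
}

# mean/sd over land cells for the continuous simulation layers
sim_layer_stats <- function(stack) {
  land <- land_mask(stack)
  lapply(list(elev = stack$layers$dem, dist_coast = stack$layers$dist_coast),
         function(g) {
           v <- g$values[land]
           list(mean = mean(v), sd = stats::sd(v))
         })
}

# covariate matrix at candidate endpoints; names are vegetation classes
# (0/1 patch indicators) or standardized continuous layers
step_covariates <- function(stack, x, y, names, stats_cache = NULL) {
  if (is.null(stats_cache)) stats_cache <- sim_layer_stats(stack)
  veg <- rg_extract(stack$layers$veg_class, x, y)
  X <- matrix(NA_real_, length(x), length(names),
              dimnames = list(NULL, names))
  for (nm in names) {
    if (nm %in% stack$class_names) {
      X[, nm] <- as.numeric(veg == match(nm, stack$class_names))
    } else if (nm == "elev") {
      s <- stats_cache$elev
      X[, nm] <- (rg_extract(stack$layers$dem, x, y) - s$mean) / s$sd
    } else if (nm == "dist_coast") {
      s <- stats_cache$dist_coast
      X[, nm] <- (rg_extract(stack$layers$dist_coast, x, y) - s$mean) / s$sd
    } else {
      stop("unknown simulation covariate: ", nm)
    }
  }
  X
}

#' Simulate GPS tracks by a step-selection rule with known coefficients
#'
#' Each animal performs a correlated random walk: at every step,
#' `n_candidates` candidate endpoints are drawn from a gamma step-length
#' distribution (mean `step_scale`) and von Mises turning angles around the
#' current heading, water/off-grid candidates are rejected (the step scale
#' widens after a fully invalid candidate set, with an error after 100
#' failures), and one endpoint is selected with probability proportional to
#' `exp(beta' x)` of its covariates. Fixes are stamped at `fix_interval`
#' hours starting 1 June of the animal's synthetic year; low-quality fix
#' records (2D fixes, PDOP > 10) are injected at the configured rates.
#' Animals are split across two synthetic years and a parturient/
#' non-parturient status, and normal random intercepts per animal and year
#' are drawn (they do not alter the step choice; they parameterize the
#' landscape-scale data generator and are reported as ground truth).
#'
#' @param landscape a `landscape_stack` from [generate_landscape()].
#' @param config a [synthetic_config()]; `names(config$true_beta)` must name
#'   vegetation classes or continuous layers available in the stack.
#' @return list with `tracks` (data.frame: animal_id, year, timestamp, x, y,
#'   fix_dim, pdop, parturient) and `truth` (list: true_beta,
#'   realized_step_lengths, realized_bearings in `[-pi, pi)`,
#'   candidate_class_counts, per_animal_intercepts, per_year_intercepts).
#' @export
simulate_tracks <- function(landscape, config) {
  stopifnot(inherits(landscape, "landscape_stack"),
            inherits(config, "synthetic_config"))
  beta <- config$true_beta
  avail_names <- c(landscape$class_names, "elev", "dist_coast")
  if (!all(names(beta) %in% avail_names)) {
    stop("true_beta names must be available covariates: ",
         paste(setdiff(names(beta), avail_names), collapse = ", "))
  }
  set.seed(config$seed + 2L)
  g <- landscape$layers$veg_class
  cs <- landscape$cell_size
  xlim <- c(g$xmin, rg_xmax(g)); ylim <- c(g$ymin, rg_ymax(g))
  land <- land_mask(landscape)
  stats_cache <- sim_layer_stats(landscape)
  K <- config$n_candidates
  shape <- 2

  land_idx <- which(land, arr.ind = TRUE)
  co <- rg_coords(g)

  years <- 2004L + (seq_len(config$n_animals) - 1L) %% 2L
  a_int <- stats::rnorm(config$n_animals, 0, config$re_sd_animal)
  y_int <- stats::rnorm(length(unique(years)), 0, config$re_sd_year)
  names(y_int) <- as.character(sort(unique(years)))
  partur <- rep(c("yes", "no"), length.out = config$n_animals)

  all_tracks <- vector("list", config$n_animals)
  step_lengths <- c(); bearings <- c()
  cand_class_counts <- stats::setNames(numeric(length(landscape$class_names)),
                                       landscape$class_names)

  for (a in seq_len(config$n_animals)) {
    start_cell <- land_idx[sample(nrow(land_idx), 1), , drop = FALSE]
    cur <- c(co$x[start_cell], co$y[start_cell])
    heading <- stats::runif(1, -pi, pi)
    n_steps <- config$n_steps_per_animal
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- cur[1]; ys[1] <- cur[2]
    for (s in seq_len(n_steps)) {
      scale_mult <- 1
      for (attempt in seq_len(100L)) {
        len <- stats::rgamma(K, shape = shape,
                             scale = scale_mult * config$step_scale / shape)
        turn <- rvonmises(K, 0, config$turn_concentration)
        brg <- wrap_angle(heading + turn)
        cx <- reflect_into(cur[1] + len * sin(brg), xlim[1], xlim[2] - 1e-9)
        cy <- reflect_into(cur[2] + len * cos(brg), ylim[1], ylim[2] - 1e-9)
        on_land <- rg_extract(landscape$layers$water, cx, cy) == 0
        on_land[is.na(on_land)] <- FALSE
        if (any(on_land)) break
        scale_mult <- scale_mult * 1.5
        if (attempt == 100L) stop("candidate sets entirely in no-data after 100 widenings")
      }
      cx <- cx[on_land]; cy <- cy[on_land]
      brg <- brg[on_land]; len <- len[on_land]
      vc <- rg_extract(landscape$layers$veg_class, cx, cy)
      tb <- tabulate(vc, nbins = length(cand_class_counts))
      cand_class_counts <- cand_class_counts + tb
      X <- step_covariates(landscape, cx, cy, names(beta), stats_cache)
      eta <- as.vector(X %*% beta)
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      pick <- sample.int(length(cx), 1, prob = pr)
      cur <- c(cx[pick], cy[pick])
      heading <- brg[pick]
      xs[s + 1] <- cur[1]; ys[s + 1] <- cur[2]
      step_lengths <- c(step_lengths, len[pick])
      bearings <- c(bearings, brg[pick])
    }
    t0 <- as.POSIXct(sprintf("%d-06-01 00:00:00", years[a]), tz = "UTC")
    ts <- t0 + (0:n_steps) * config$fix_interval * 3600
    all_tracks[[a]] <- data.frame(
      animal_id = sprintf("A%02d", a), year = years[a], timestamp = ts,
      x = xs, y = ys, parturient = partur[a], stringsAsFactors = FALSE
    )
  }
  tracks <- do.call(rbind, all_tracks)

  # injected low-quality records
  n <- nrow(tracks)
  u <- stats::runif(n)
  tracks$fix_dim <- ifelse(u < config$p_2d, "2D", "3D")
  hi <- u >= config$p_2d & u < config$p_2d + config$p_highpdop
  tracks$pdop <- ifelse(hi, stats::runif(n, 10.5, 20), stats::runif(n, 1, 6))

  truth <- list(
    true_beta = beta,
    realized_step_lengths = step_lengths,
    realized_bearings = bearings,
    candidate_class_counts = cand_class_counts,
    per_animal_intercepts = stats::setNames(a_int,
                                            sprintf("A%02d", seq_len(config$n_animals))),
    per_year_intercepts = y_int
  )
  list(tracks = tracks, truth = truth)
}
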