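#' Pipeline run configuration
#'
#' Collects every constant of the analysis (screening thresholds, season
#' calendar, insect index settings, sampling ratios, model/validation
#' settings) plus either a synthetic-data configuration or paths to input
#' files. All thresholds are validated here so a bad configuration fails
#' before any computation.
#'
#' @param synthetic a [synthetic_config()] for a self-contained run, or
#'   `NULL` when `paths` supplies real inputs.
#' @param paths named list of input files (`fixes`, `weather`, rasters);
#'   checked for existence when `synthetic` is `NULL`.
#' @param seasons seasons to fit (subset of the calendar names).
#' @param pdop_max,min_move,insect_lookback,vif_threshold,isopleth,n_per_used
#'   analysis constants (PDOP cut-off, sedentary displacement in m,
#'   insect look-back in hours, VIF cut-off, range isopleth level,
#'   available points per used step).
#' @param kfold_k,kfold_bins cross-validation settings.
#' @param seed master seed; stage seeds are derived from it.
#' @param output_dir optional directory for manifests, tables and surfaces.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       paths = list(),
                       seasons = c("post_calving", "mosquito"),
                       pdop_max = 10, min_move = 25,
                       insect_lookback = 12, vif_threshold = 3,
                       isopleth = 0.95, n_per_used = 5,
                       kfold_k = 5, kfold_bins = 10,
                       seed = 1L, output_dir = NULL) {
  stopifnot(pdop_max > 0, min_move > 0, insect_lookback > 0,
            vif_threshold > 0, isopleth > 0, isopleth <= 1,
            n_per_used >= 1, kfold_k >= 2, kfold_bins >= 2)
  stopifnot(all(seasons %in% season_calendar()$season))
  if (is.null(synthetic)) {
    required <- c("fixes", "weather", "veg", "dem", "coast", "water")
    missing <- setdiff(required, names(paths))
    if (length(missing) > 0) {
      stop("missing input paths: ", paste(missing, collapse = ", "))
    }
    absent <- names(paths)[!vapply(paths, file.exists, logical(1))]
    if (length(absent) > 0) {
      stop("input files not found: ", paste(absent, collapse = ", "))
    }
  }
  structure(as.list(environment()), class = "run_config")
}

pipeline_group_defs <- function(season) {
  switch(season,
    calving = list(list(tag = "calving_parturient", partur = "yes"),
                   list(tag = "calving_nonparturient", partur = "no")),
    mosquito = list(list(tag = "mosquito_high", insect = "high",
                         species = "mosquito"),
                    list(tag = "mosquito_low", insect = "low",
                         species = "mosquito")),
    oestrid_fly = list(list(tag = "fly_high", insect = "high",
                            species = "fly"),
                       list(tag = "fly_low", insect = "low",
                            species = "fly")),
    list(list(tag = season))
  )
}

#' Run the full two-scale selection analysis
#'
#' Executes the complete pipeline: data generation (or loading), fix
#' screening, sedentary filtering, season assignment, herd-switch
#' exclusion, insect-period classification, covariate-layer construction,
#' used-available sampling at both scales, VIF pruning, non-linearity
#' screening, model fitting (random-intercept logistic at the landscape
#' scale; all-subsets AIC conditional logistic at the patch scale),
#' residual-autocorrelation-robust standard errors, k-fold validation, and
#' relative-probability-of-use surfaces. Returns a manifest of per-stage
#' counts, fitted coefficients and validation summaries enabling
#' reproducible reruns; artefacts are written under `output_dir` when set.
#'
#' @param config a [run_config()].
#' @return the run manifest (list), invisibly classed `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(seed = config$seed, seasons = config$seasons,
                   thresholds = config[c("pdop_max", "min_move",
                                         "insect_lookback", "vif_threshold",
                                         "isopleth", "n_per_used")])

  # --- stage: inputs -------------------------------------------------
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    stack <- generate_landscape(sc)
    sim <- simulate_tracks(stack, sc)
    raw <- sim$tracks
    yrs <- sort(unique(raw$year))
    weather <- do.call(rbind, lapply(yrs, function(yy) {
      simulate_weather(sc,
                       as.POSIXct(sprintf("%d-05-31 00:00:00", yy), tz = "UTC"),
                       as.POSIXct(sprintf("%d-09-16 00:00:00", yy), tz = "UTC"))
    }))
    manifest$truth <- list(true_beta = as.list(sim$truth$true_beta))
  } else {
    raw <- read_fix_csv(config$paths$fixes)
    weather <- read_weather_csv(config$paths$weather)
    stack <- load_landscape(config$paths)
  }
  manifest$counts <- list(n_raw_fixes = nrow(raw))

  # --- stage: preprocessing ------------------------------------------
  scr <- screen_fixes(raw, pdop_max = config$pdop_max)
  manifest$screen_report <- scr$report
  fixes <- assign_seasons(scr$fixes)
  fixes <- filter_sedentary(fixes, min_move = config$min_move)
  hs <- flag_herd_switch(fixes)
  fixes <- hs$fixes
  manifest$counts$n_analysis_fixes <- nrow(fixes)
  manifest$counts$n_by_season <- as.list(table(fixes$season))

  # --- stage: insect classification ----------------------------------
  for (sp in c("mosquito", "fly")) {
    par <- insect_params(sp)
    par$lookback <- config$insect_lookback
    fixes[[paste0("insect_", sp)]] <-
      classify_insect_period(fixes$timestamp, weather, par)
  }
  manifest$counts$n_insect_unknown <-
    sum(fixes$insect_mosquito == "unknown")

  # --- stage: covariate layers ---------------------------------------
  stack <- add_covariate_layers(stack)
  manifest$ttlqv_scales_m <- as.list(stack$ttlqv_scales)

  land_covs <- c("veg_patch",
                 paste0("density_", names(stack$ttlqv_scales)),
                 "greenup", "maxgrowth", "elev", "dist_coast", "vrm",
                 "precip")
  patch_blocks <- list(veg = NULL, elev = "elev",
                       dist_coast = "dist_coast", vrm = "vrm")

  manifest$groups <- list()
  for (season in config$seasons) {
    sfix <- fixes[fixes$season == season, , drop = FALSE]
    for (gd in pipeline_group_defs(season)) {
      g <- sfix
      if (!is.null(gd$partur)) g <- g[g$parturient == gd$partur, , drop = FALSE]
      if (!is.null(gd$insect)) {
        g <- g[g[[paste0("insect_", gd$species)]] == gd$insect, , drop = FALSE]
      }
      if (nrow(g) < 60 || length(unique(g$animal_id)) < max(2, config$kfold_k)) {
        manifest$groups[[gd$tag]] <- list(skipped = TRUE, n_fixes = nrow(g))
        next
      }
      manifest$groups[[gd$tag]] <-
        tryCatch(fit_group(g, stack, config, land_covs, patch_blocks),
                 error = function(e) list(error = conditionMessage(e)))
    }
  }

  if (!is.null(config$output_dir)) write_run_outputs(manifest, config)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

# landscape + patch analysis for one season/status/insect group
fit_group <- function(g, stack, config, land_covs, patch_blocks) {
  out <- list(n_fixes = nrow(g), n_animals = length(unique(g$animal_id)))

  # landscape scale: 1:1 availability within the 95% KDE isopleth
  rng <- kde_range(g, level = config$isopleth,
                   cellsize = 2 * stack$cell_size)
  avail <- sample_available_landscape(rng, nrow(g), stack,
                                      seed = config$seed + 11L)
  avail$animal_id <- g$animal_id; avail$year <- g$year
  avail$timestamp <- g$timestamp
  used <- g[, c("x", "y", "animal_id", "year", "timestamp")]
  tab <- rbind(cbind(used, used = 1L),
               cbind(avail[, names(used)], used = 0L))
  ct <- build_design(tab, stack, covariates = land_covs)
  cont <- setdiff(attr(ct, "covariate_cols"),
                  grep("^patch_", attr(ct, "covariate_cols"), value = TRUE))
  vp <- vif_prune(ct[, cont, drop = FALSE], config$vif_threshold)
  qs <- quadratic_screen(ct, intersect(c("elev", "dist_coast", "vrm"),
                                       vp$retained))
  covs <- c(grep("^patch_", attr(ct, "covariate_cols"), value = TRUE),
            vp$retained)
  for (sq in qs$squared) {
    ct[[paste0(sq, "_sq")]] <- ct[[sq]]^2
    covs <- c(covs, paste0(sq, "_sq"))
    attr(ct, "covariate_cols") <- c(attr(ct, "covariate_cols"),
                                    paste0(sq, "_sq"))
  }
  lfit <- fit_mixed_logistic(ct, covs)
  llag <- residual_lag(lfit, ct)
  lfit <- robust_refit(lfit, ct, llag$lag)
  lval <- kfold_validate(ct, function(d) fit_mixed_logistic(d, covs),
                         k = config$kfold_k, bins = config$kfold_bins,
                         seed = config$seed + 12L)
  surf <- predict_surface(lfit, stack, ct)
  out$landscape <- list(
    n_used = sum(tab$used), vif_dropped = vp$dropped,
    squared_added = qs$squared, residual_lag = llag$lag,
    coefficients = fit_to_list(lfit),
    rho_mean = lval$rho_mean, rho_p = lval$p_value)
  out$landscape_surface <- surf

  # patch scale: 5:1 matched steps, all-subsets AIC
  steps <- sample_available_steps(g, n_per_used = config$n_per_used,
                                  stack = stack,
                                  seed = config$seed + 13L)
  pct <- build_design(steps, stack,
                      covariates = c("veg_patch", "elev", "dist_coast",
                                     "vrm"))
  # strata losing rows to water keep exactly 1 used + n available
  ok_str <- names(which(tapply(pct$used, pct$stratum, function(u)
    sum(u) == 1 & length(u) == config$n_per_used + 1)))
  pct2 <- pct[as.character(pct$stratum) %in% ok_str, , drop = FALSE]
  for (a in c("covariate_cols", "scaling", "squared", "reference_class")) {
    attr(pct2, a) <- attr(pct, a)
  }
  blocks <- patch_blocks
  blocks$veg <- grep("^patch_", attr(pct, "covariate_cols"), value = TRUE)
  sel <- all_subsets_aic(pct2, blocks)
  pfit <- sel$best_fit
  plag <- residual_lag(pfit, pct2)
  pfit <- robust_refit(pfit, pct2, plag$lag)
  pval <- kfold_validate(pct2, function(d)
    fit_conditional_logistic(d, pfit$covariates),
    k = min(config$kfold_k, out$n_animals), bins = config$kfold_bins,
    seed = config$seed + 14L)
  out$patch <- list(
    n_strata = length(ok_str),
    n_dropped_strata = attr(steps, "n_dropped_strata"),
    best_blocks = sel$best_blocks, residual_lag = plag$lag,
    coefficients = fit_to_list(pfit),
    rho_mean = pval$rho_mean, rho_p = pval$p_value)
  out
}

fit_to_list <- function(fit) {
  out <- list(beta = as.list(fit$beta),
              se_naive = as.list(fit$se_naive),
              aic = fit$aic)
  if (!is.na(fit$intercept)) out$intercept <- fit$intercept
  if (!is.null(fit$se_robust)) {
    out$se_robust <- as.list(fit$se_robust)
    out$significant <- as.list(fit$significant)
  }
  if (!is.null(fit$re_sd) && length(fit$re_sd)) out$re_sd <- as.list(fit$re_sd)
  out
}

write_run_outputs <- function(manifest, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  m <- manifest
  for (g in names(m$groups)) {
    surf <- m$groups[[g]]$landscape_surface
    if (!is.null(surf)) {
      write_ascii_grid(surf$w, file.path(config$output_dir,
                                         paste0("w_", g, ".asc")))
    }
    m$groups[[g]]$landscape_surface <- NULL
  }
  jsonlite::write_json(m, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
}

#' Read GPS fixes from CSV
#'
#' Expected columns: `animal_id`, `timestamp` (ISO-8601, UTC), `x`, `y`,
#' `fix_dim`, `pdop`; optional `year`, `parturient`.
#'
#' @param path CSV file.
#' @return data.frame with POSIXct timestamps.
#' @export
read_fix_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
  if (!"year" %in% names(d)) {
    d$year <- as.integer(format(d$timestamp, "%Y", tz = "UTC"))
  }
  d
}

#' Read a weather-station series from CSV
#'
#' Expected columns: `station_id`, `timestamp` (ISO-8601, UTC), `temp_c`,
#' `wind_ms`.
#'
#' @param path CSV file.
#' @return a `weather_series` data.frame.
#' @export
read_weather_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
  class(d) <- c("weather_series", "data.frame")
  d
}

# assemble a landscape_stack from ASCII-grid input files
load_landscape <- function(paths) {
  lay <- list(veg_class = read_ascii_grid(paths$veg),
              dem = read_ascii_grid(paths$dem),
              coast = read_ascii_grid(paths$coast),
              water = read_ascii_grid(paths$water))
  if (!is.null(paths$precip)) lay$precip <- read_ascii_grid(paths$precip)
  ndvi <- NULL
  if (!is.null(paths$ndvi)) {
    grids <- lapply(paths$ndvi, read_ascii_grid)
    dates <- as.numeric(names(paths$ndvi))
    ndvi <- list(dates = dates, grids = grids)
  }
  cls <- sort(unique(as.vector(lay$veg_class$values)))
  structure(list(layers = lay, ndvi = ndvi,
                 class_names = paste0("class_", cls),
                 cell_size = lay$veg_class$cellsize),
            class = "landscape_stack")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  raw fixes:", x$counts$n_raw_fixes,
      "| analysis fixes:", x$counts$n_analysis_fixes, "\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    if (isTRUE(gr$skipped)) { cat("  ", g, ": skipped\n"); next }
    if (!is.null(gr$error)) { cat("  ", g, ": ERROR ", gr$error, "\n"); next }
    cat(sprintf("  %s: landscape rho=%.3f, patch rho=%.3f (%d strata)\n",
                g, gr$landscape$rho_mean, gr$patch$rho_mean,
                gr$patch$n_strata))
  }
  invisible(x)
}
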