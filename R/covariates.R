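# summed-area box sums with truncated (clamped) windows; NA treated as 0
box_sum <- function(m, lo_off, hi_off) {
  nr <- nrow(m); nc <- ncol(m)
  m0 <- m; m0[is.na(m0)] <- 0
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m0, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) + lo_off, 1L); r2 <- pmin(seq_len(nr) + hi_off, nr)
  c1 <- pmax(seq_len(nc) + lo_off, 1L); c2 <- pmin(seq_len(nc) + hi_off, nc)
  R2 <- S[r2 + 1, , drop = FALSE]; R1 <- S[r1, , drop = FALSE]
  (R2[, c2 + 1, drop = FALSE] - R2[, c1, drop = FALSE]) -
    (R1[, c2 + 1, drop = FALSE] - R1[, c1, drop = FALSE])
}

#' Scale of maximum patchiness by three-term local quadrat variance
#'
#' Computes the three-term local quadrat variance of the 0/1 indicator of a
#' vegetation class over block sizes `b = 1..max_block`:
#' `V3(b) = mean over positions of (S1 - 2*S2 + S3)^2 / (8*b)` where
#' `S1, S2, S3` are sums over three consecutive length-`b` blocks along a
#' transect. Transects are taken along both rows and columns and the two
#' mean curves averaged; the returned scale is the block size maximizing
#' the averaged curve, converted to metres. This is the window size at
#' which a moving-window density layer captures the strongest spatial
#' variation for that class.
#'
#' @param veg a `raster_grid` of integer class codes.
#' @param class_k class code (or name resolved by the caller).
#' @param max_block largest block size in cells (clamped to a third of the
#'   shorter grid side).
#' @return list `scale_m`, `b_star`, and `v3` (data.frame `b`, `v3`).
#' @export
ttlqv_scale <- function(veg, class_k, max_block = 32) {
  ind <- (veg$values == class_k) + 0
  ind[is.na(veg$values)] <- NA
  n1 <- sum(ind == 1, na.rm = TRUE)
  if (n1 == 0) stop("degenerate indicator: class absent from raster")
  if (n1 == sum(!is.na(ind))) stop("degenerate indicator: class fills raster")
  max_block <- min(max_block, floor(min(dim(ind)) / 3))
  stopifnot(max_block >= 2)
  ind0 <- ind; ind0[is.na(ind0)] <- 0

  v3_transects <- function(m, b) {
    # rows of m are transects; returns mean of squared third differences
    n <- ncol(m)
    if (n < 3 * b) return(NA_real_)
    cs <- cbind(0, t(apply(m, 1, cumsum)))
    S <- function(start) cs[, start + b] - cs[, start]
    i <- seq_len(n - 3 * b + 1)
    tt <- S(i) - 2 * S(i + b) + S(i + 2 * b)
    mean(tt^2) / (8 * b)
  }
  bs <- seq_len(max_block)
  v3 <- vapply(bs, function(b) {
    mean(c(v3_transects(ind0, b), v3_transects(t(ind0), b)), na.rm = TRUE)
  }, numeric(1))
  b_star <- bs[which.max(v3)]
  list(scale_m = b_star * veg$cellsize, b_star = b_star,
       v3 = data.frame(b = bs, v3 = v3))
}

#' Moving-window density of a vegetation class
#'
#' Each cell receives the proportion of class-`class_k` cells among the
#' non-missing cells of the centred square window (side
#' `round(window_m / cellsize)`, forced odd); windows are truncated at the
#' grid edge. Cells flagged in `exclude` (e.g. water) count as missing.
#'
#' @param veg `raster_grid` of class codes.
#' @param class_k class code.
#' @param window_m window side (m).
#' @param exclude optional logical matrix of cells to treat as no-data.
#' @return `raster_grid` of densities in \[0, 1\].
#' @export
moving_window_density <- function(veg, class_k, window_m, exclude = NULL) {
  w <- round(window_m / veg$cellsize)
  if (w < 1) w <- 1
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  valid <- !is.na(veg$values)
  if (!is.null(exclude)) valid <- valid & !exclude
  ind <- (veg$values == class_k) & valid
  num <- box_sum(ind + 0, -half, half)
  den <- box_sum(valid + 0, -half, half)
  out <- num / den
  out[den == 0] <- NA
  raster_grid(out, veg$xmin, veg$ymin, veg$cellsize)
}

#' Vector ruggedness measure of a DEM
#'
#' Terrain ruggedness as the dispersion of unit vectors normal to the
#' surface: slope/aspect are taken per cell by Horn's eight-neighbour
#' finite differences (edges padded by replication), each cell contributes
#' the unit normal `(-gx, -gy, 1)/sqrt(1 + gx^2 + gy^2)`, and
#' `vrm = 1 - ||sum of normals|| / n` over a square moving window of
#' `window` cells per side (truncated at edges). 0 for any planar surface,
#' approaching 1 for maximally disordered terrain; invariant to adding a
#' constant to the DEM.
#'
#' @param dem `raster_grid` of elevations (m).
#' @param window window side in cells (default 8; even windows are centred
#'   with the extra cell to the south/east).
#' @return `raster_grid` of VRM values in \[0, 1\].
#' @export
vrm <- function(dem, window = 8) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  stopifnot(nr * nc >= window^2)
  cs <- dem$cellsize
  # linear-extrapolation padding keeps the gradient of a planar DEM exact
  # at the edges (replication would halve it there)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  if (nr >= 2) {
    zp[1, ] <- 2 * zp[2, ] - zp[3, ]
    zp[nr + 2, ] <- 2 * zp[nr + 1, ] - zp[nr, ]
  }
  if (nc >= 2) {
    zp[, 1] <- 2 * zp[, 2] - zp[, 3]
    zp[, nc + 2] <- 2 * zp[, nc + 1] - zp[, nc]
  }
  sh <- function(dr, dc) zp[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * cs)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
           (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * cs)
  len <- sqrt(1 + gx^2 + gy^2)
  nx <- -gx / len; ny <- -gy / len; nz <- 1 / len
  lo <- -floor((window - 1) / 2); hi <- floor(window / 2)
  sx <- box_sum(nx, lo, hi); sy <- box_sum(ny, lo, hi)
  sz <- box_sum(nz, lo, hi); n <- box_sum(matrix(1, nr, nc), lo, hi)
  v <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n
  v[v < 0] <- 0; v[v > 1] <- 1
  raster_grid(v, dem$xmin, dem$ymin, cs)
}

#' Phenology dates from an NDVI composite stack
#'
#' Per pixel: green-up is the first composite date whose NDVI exceeds the
#' no-growth background of 0.1; maximum growth is the date of the maximum
#' NDVI (earliest date on ties); senescence is the first date after maximum
#' growth with NDVI below 0.1. Pixels never exceeding 0.1 get `NA` for all
#' three dates.
#'
#' @param ndvi list with `dates` (day-of-year) and `grids` (list of
#'   `raster_grid`), as in a `landscape_stack`.
#' @return list of `raster_grid`s: `greenup_date`, `maxgrowth_date`,
#'   `senescence_date` (day-of-year).
#' @export
ndvi_phenology <- function(ndvi) {
  stopifnot(length(ndvi$grids) >= 3)
  dates <- ndvi$dates
  M <- vapply(ndvi$grids, function(g) as.vector(g$values),
              numeric(length(ndvi$grids[[1]]$values)))
  ex <- M > 0.1
  any_ex <- rowSums(ex) > 0
  gu_i <- max.col(ex + 0, ties.method = "first")
  mx_i <- max.col(M, ties.method = "first")
  after_low <- ((!ex) & (col(M) > mx_i)) + 0
  sen_any <- rowSums(after_low) > 0
  sen_i <- max.col(after_low, ties.method = "first")
  gu <- ifelse(any_ex, dates[gu_i], NA)
  mx <- ifelse(any_ex, dates[mx_i], NA)
  sen <- ifelse(any_ex & sen_any, dates[sen_i], NA)
  g1 <- ndvi$grids[[1]]
  shape <- dim(g1$values)
  mk <- function(v) raster_grid(matrix(v, shape[1], shape[2]),
                                g1$xmin, g1$ymin, g1$cellsize)
  list(greenup_date = mk(gu), maxgrowth_date = mk(mx),
       senescence_date = mk(sen))
}

#' Euclidean distance to the nearest coast cell
#'
#' @param coast `raster_grid` with 1 on coast cells, 0 elsewhere.
#' @return `raster_grid` of distances (m) between cell centres.
#' @export
distance_to_coast <- function(coast) {
  cc <- which(coast$values == 1)
  if (length(cc) == 0) stop("empty coast mask")
  co <- rg_coords(coast)
  xc <- co$x[cc]; yc <- co$y[cc]
  n <- length(coast$values)
  out <- numeric(n)
  chunk <- 4000L
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(s + chunk - 1L, n)
    d2 <- outer(co$x[i], xc, "-")^2 + outer(co$y[i], yc, "-")^2
    out[i] <- sqrt(apply(d2, 1, min))
  }
  raster_grid(matrix(out, nrow(coast$values), ncol(coast$values)),
              coast$xmin, coast$ymin, coast$cellsize)
}

#' Add derived covariate layers to a landscape stack
#'
#' Computes, for each vegetation class present, the TTLQV scale of maximum
#' variation and the moving-window density at that scale
#' (`density_<class>`); the vector ruggedness measure; the NDVI phenology
#' date layers; and (if absent) distance to coast. Water cells are excluded
#' from density windows.
#'
#' @param stack a `landscape_stack`.
#' @param max_block TTLQV search limit (cells).
#' @param vrm_window VRM window (cells).
#' @return the stack with layers added and a `ttlqv_scales` element
#'   (named vector, metres).
#' @export
add_covariate_layers <- function(stack, max_block = 32, vrm_window = 8) {
  veg <- stack$layers$veg_class
  water <- stack$layers$water$values == 1
  scales <- numeric(0)
  for (k in seq_along(stack$class_names)) {
    nm <- stack$class_names[k]
    if (!any(veg$values == k & !water, na.rm = TRUE)) next
    sc <- tryCatch(ttlqv_scale(veg, k, max_block)$scale_m,
                   error = function(e) 3 * veg$cellsize)
    scales[nm] <- sc
    stack$layers[[paste0("density_", nm)]] <-
      moving_window_density(veg, k, sc, exclude = water)
  }
  stack$layers$vrm <- vrm(stack$layers$dem, vrm_window)
  ph <- ndvi_phenology(stack$ndvi)
  stack$layers <- c(stack$layers, ph)
  if (is.null(stack$layers$dist_coast)) {
    stack$layers$dist_coast <- distance_to_coast(stack$layers$coast)
  }
  stack$ttlqv_scales <- scales
  stack
}

# transformed (but unstandardized) covariate layer as a matrix
covariate_layer <- function(stack, name) {
  cs <- stack$cell_size
  switch(name,
    elev = log(stack$layers$dem$values + cs),
    dist_coast = log(stack$layers$dist_coast$values + cs),
    vrm = sqrt(stack$layers$vrm$values),
    greenup = stack$layers$greenup_date$values,
    maxgrowth = stack$layers$maxgrowth_date$values,
    senescence = stack$layers$senescence_date$values,
    precip = stack$layers$precip$values,
    {
      if (startsWith(name, "density_")) {
        g <- stack$layers[[name]]
        if (is.null(g)) stop("no density layer for covariate: ", name)
        g$values
      } else stop("unknown covariate: ", name)
    }
  )
}

#' Assemble a standardized design table at point locations
#'
#' Extracts the requested covariates at the supplied points, applying the
#' standard transforms (log for elevation and distance to coast with a
#' one-cell guard against zeros, square root for ruggedness), one-hot
#' encodes the vegetation patch type with sedge-grass meadow omitted as the
#' reference class, z-standardizes each continuous column over the supplied
#' (used + available) fitting set, and appends squared terms of the
#' standardized columns where requested. Points on water or no-data are
#' dropped with a count. Standardization statistics are stored so that map
#' prediction can apply the identical scaling.
#'
#' @param points data.frame with `x`, `y` and any metadata columns (`used`,
#'   `stratum`, `animal_id`, ... pass through).
#' @param stack a `landscape_stack` (with [add_covariate_layers()] applied
#'   if density/vrm/phenology covariates are requested).
#' @param covariates character vector: `"veg_patch"` plus any of `"elev"`,
#'   `"dist_coast"`, `"vrm"`, `"precip"`, `"greenup"`, `"maxgrowth"`,
#'   `"senescence"`, `"density_<class>"`.
#' @param squared standardized columns to square (e.g. `"vrm"`).
#' @param reference_class vegetation class omitted from the dummies.
#' @return a `covariate_table` data.frame with attributes `covariate_cols`,
#'   `scaling` (per-column mean/sd), `squared`, `reference_class`,
#'   `n_dropped_nodata`.
#' @export
build_design <- function(points, stack,
                         covariates = c("veg_patch", "elev", "dist_coast",
                                        "vrm"),
                         squared = character(0),
                         reference_class = "sedge_grass_meadow") {
  veg <- rg_extract(stack$layers$veg_class, points$x, points$y)
  water <- rg_extract(stack$layers$water, points$x, points$y)
  cont_names <- setdiff(covariates, "veg_patch")
  cont <- lapply(cont_names, function(nm) {
    g <- stack$layers$veg_class
    rg_extract(raster_grid(covariate_layer(stack, nm), g$xmin, g$ymin,
                           g$cellsize),
               points$x, points$y)
  })
  names(cont) <- cont_names
  ok <- !is.na(veg) & !is.na(water) & water == 0
  for (v in cont) ok <- ok & !is.na(v)
  n_drop <- sum(!ok)

  out <- points[ok, , drop = FALSE]
  cols <- character(0)
  if ("veg_patch" %in% covariates) {
    keep <- setdiff(stack$class_names, reference_class)
    for (nm in keep) {
      col <- paste0("patch_", nm)
      out[[col]] <- as.numeric(stack$class_names[veg[ok]] == nm)
      cols <- c(cols, col)
    }
  }
  scaling <- list()
  for (nm in cont_names) {
    v <- cont[[nm]][ok]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    out[[nm]] <- (v - m) / s
    scaling[[nm]] <- c(mean = m, sd = s)
    cols <- c(cols, nm)
  }
  for (nm in intersect(squared, cont_names)) {
    col <- paste0(nm, "_sq")
    out[[col]] <- out[[nm]]^2
    cols <- c(cols, col)
  }
  rownames(out) <- NULL
  structure(out,
            covariate_cols = cols, scaling = scaling, squared = squared,
            reference_class = reference_class, n_dropped_nodata = n_drop,
            class = c("covariate_table", "data.frame"))
}

#' Iterative variance-inflation-factor pruning
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for every column (R^2 from regressing
#' the column on all others, with intercept) and repeatedly drops the single
#' highest-VIF column while any VIF exceeds `threshold`, recomputing after
#' each drop. Perfectly collinear columns get infinite VIF and fall first;
#' constant columns get VIF 1.
#'
#' @param X numeric matrix or data.frame of candidate columns.
#' @param threshold VIF cut-off (columns with VIF > threshold are dropped).
#' @return list `retained` (column names), `dropped` (in drop order),
#'   `vif` (final VIFs of retained columns).
#' @export
vif_prune <- function(X, threshold = 3) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, is.numeric(X))
  vif_one <- function(M, j) {
    yj <- M[, j]
    ss_tot <- sum((yj - mean(yj))^2)
    if (ss_tot == 0) return(1)
    fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2) break
    v <- vapply(seq_len(ncol(X)), function(j) vif_one(X, j), numeric(1))
    names(v) <- colnames(X)
    if (max(v) <= threshold) break
    worst <- which.max(v)
    dropped <- c(dropped, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  v_final <- if (ncol(X) >= 2) {
    stats::setNames(vapply(seq_len(ncol(X)), function(j) vif_one(X, j),
                           numeric(1)), colnames(X))
  } else stats::setNames(rep(1, ncol(X)), colnames(X))
  list(retained = colnames(X), dropped = dropped, vif = v_final)
}
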