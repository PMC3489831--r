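# Independent brute-force oracles. These deliberately use nested loops and
# naive formulas so they share no code path with the package.

# three-term local quadrat variance of a 0/1 matrix, rows+columns averaged
oracle_v3 <- function(ind, b) {
  one_dir <- function(m) {
    n <- ncol(m)
    if (n < 3 * b) return(NULL)
    vals <- c()
    for (r in seq_len(nrow(m))) {
      for (i in seq_len(n - 3 * b + 1)) {
        s1 <- sum(m[r, i:(i + b - 1)])
        s2 <- sum(m[r, (i + b):(i + 2 * b - 1)])
        s3 <- sum(m[r, (i + 2 * b):(i + 3 * b - 1)])
        vals <- c(vals, (s1 - 2 * s2 + s3)^2)
      }
    }
    mean(vals) / (8 * b)
  }
  mean(c(one_dir(ind), one_dir(t(ind))))
}

oracle_ttlqv_bstar <- function(ind, max_block) {
  v3 <- sapply(seq_len(max_block), function(b) oracle_v3(ind, b))
  which.max(v3)
}

# per-cell moving-window class proportion by explicit counting
oracle_density <- function(veg, k, w_cells) {
  half <- (w_cells - 1) / 2
  nr <- nrow(veg); nc <- ncol(veg)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    cj <- max(1, j - half):min(nc, j + half)
    win <- veg[ri, cj]
    out[i, j] <- sum(win == k, na.rm = TRUE) / sum(!is.na(win))
  }
  out
}

# vector ruggedness by explicit per-cell normals and window vector sums
oracle_vrm <- function(z, cs, window) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  zp[1, ] <- 2 * zp[2, ] - zp[3, ]
  zp[nr + 2, ] <- 2 * zp[nr + 1, ] - zp[nr, ]
  zp[, 1] <- 2 * zp[, 2] - zp[, 3]
  zp[, nc + 2] <- 2 * zp[, nc + 1] - zp[, nc]
  nx <- ny <- nz <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + 1; jj <- j + 1
    gx <- ((zp[ii - 1, jj + 1] + 2 * zp[ii, jj + 1] + zp[ii + 1, jj + 1]) -
             (zp[ii - 1, jj - 1] + 2 * zp[ii, jj - 1] + zp[ii + 1, jj - 1])) /
      (8 * cs)
    gy <- ((zp[ii - 1, jj - 1] + 2 * zp[ii - 1, jj] + zp[ii - 1, jj + 1]) -
             (zp[ii + 1, jj - 1] + 2 * zp[ii + 1, jj] + zp[ii + 1, jj + 1])) /
      (8 * cs)
    l <- sqrt(1 + gx^2 + gy^2)
    nx[i, j] <- -gx / l; ny[i, j] <- -gy / l; nz[i, j] <- 1 / l
  }
  lo <- -floor((window - 1) / 2); hi <- floor(window / 2)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i + lo):min(nr, i + hi)
    cj <- max(1, j + lo):min(nc, j + hi)
    sx <- sum(nx[ri, cj]); sy <- sum(ny[ri, cj]); sz <- sum(nz[ri, cj])
    out[i, j] <- 1 - sqrt(sx^2 + sy^2 + sz^2) / (length(ri) * length(cj))
  }
  out
}

# all-pairs minimum distance to coast cells
oracle_dist_coast <- function(coast_vals, cs) {
  nr <- nrow(coast_vals); nc <- ncol(coast_vals)
  cells <- which(coast_vals == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dmin <- Inf
    for (p in seq_len(nrow(cells))) {
      d <- sqrt(((i - cells[p, 1]) * cs)^2 + ((j - cells[p, 2]) * cs)^2)
      if (d < dmin) dmin <- d
    }
    out[i, j] <- dmin
  }
  out
}

# even-odd ray casting point-in-polygon (poly: open ring, 2-col matrix)
oracle_ray_cast <- function(poly, px, py) {
  n <- nrow(poly)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# conditional log-likelihood for a single coefficient, evaluated on a grid
oracle_clogit_grid <- function(x, y, strata, grid) {
  ll <- vapply(grid, function(b) {
    eta <- b * x
    tot <- 0
    for (s in unique(strata)) {
      i <- strata == s
      tot <- tot + eta[i][y[i] == 1] - log(sum(exp(eta[i])))
    }
    tot
  }, numeric(1))
  grid[which.max(ll)]
}

# iterative VIF pruning recomputed with stats::lm (independent route)
oracle_vif_prune <- function(df, threshold = 3) {
  df <- as.data.frame(df)
  repeat {
    if (ncol(df) < 2) break
    v <- sapply(names(df), function(nm) {
      fml <- stats::as.formula(paste0("`", nm, "` ~ ."))
      r2 <- summary(stats::lm(fml, data = df))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    })
    if (max(v) <= threshold) break
    df[[names(df)[which.max(v)]]] <- NULL
  }
  names(df)
}
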