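#' Boyce-style k-fold cross-validation of a selection model
#'
#' Partitions animals into `k` folds; for each fold the model is refitted
#' on the remaining animals and the withheld used and available points are
#' scored with the fixed-effect linear predictor. The withheld available
#' scores define `bins` equal-count (equal-area in selection score) bins;
#' withheld used points are tallied per bin and divided by their
#' expected-under-uniform count, and the Spearman rank correlation between
#' bin rank and this area-adjusted frequency is computed per fold. The
#' summary is the fold mean; the p-value is a one-sided (increasing)
#' Spearman test on the fold-averaged frequencies.
#'
#' @param table used-available table (needs `used`, `animal_id`).
#' @param fitter function(table) returning an `rsf_fit` (e.g. a closure
#'   around [fit_mixed_logistic()] or [fit_conditional_logistic()]).
#' @param k number of folds (animals permit fewer: folds without used
#'   points are skipped with a warning).
#' @param bins selection-score bins.
#' @param seed integer seed for the animal partition.
#' @return object of class `validation_result`: `rho_mean`, `p_value`,
#'   `per_fold_rho`, `k`, `bins`, `bin_freq` (fold-averaged frequencies).
#' @export
kfold_validate <- function(table, fitter, k = 5, bins = 10, seed = 1L) {
  stopifnot(k >= 2)
  set.seed(seed)
  animals <- unique(table$animal_id)
  stopifnot(length(animals) >= k)
  fold_of <- sample(rep(seq_len(k), length.out = length(animals)))
  names(fold_of) <- animals
  rhos <- numeric(0)
  freq_mat <- matrix(NA_real_, k, bins)
  for (f in seq_len(k)) {
    test <- table[fold_of[table$animal_id] == f, , drop = FALSE]
    train <- table[fold_of[table$animal_id] != f, , drop = FALSE]
    if (sum(test$used) == 0 || sum(train$used) == 0) {
      warning("fold ", f, " has no used points; skipped")
      next
    }
    fit <- fitter(train)
    X <- as.matrix(test[, fit$covariates, drop = FALSE])
    score <- as.vector(X %*% fit$beta)
    br <- stats::quantile(score[test$used == 0],
                          probs = seq(0, 1, length.out = bins + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    br <- unique(br)
    nb <- length(br) - 1
    bin <- cut(score[test$used == 1], br, labels = FALSE)
    obs <- tabulate(bin, nbins = nb)
    expd <- sum(obs) / nb
    freq <- obs / expd
    rhos <- c(rhos, stats::cor(seq_len(nb), freq, method = "spearman"))
    freq_mat[f, seq_len(nb)] <- freq
  }
  if (length(rhos) == 0) stop("no fold could be validated")
  mean_freq <- colMeans(freq_mat, na.rm = TRUE)
  ct <- suppressWarnings(
    stats::cor.test(seq_len(bins), mean_freq, method = "spearman",
                    alternative = "greater"))
  structure(list(rho_mean = mean(rhos), p_value = ct$p.value,
                 per_fold_rho = rhos, k = k, bins = bins,
                 bin_freq = mean_freq),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> k=%d folds, rho_mean = %.3f, P = %.4g\n",
              x$k, x$rho_mean, x$p_value))
  invisible(x)
}

# standardized design matrix over all grid cells, using the scaling stored
# on a covariate_table; returns list(X, land) with X ncell x p (column-major
# cell order)
design_for_cells <- function(stack, ct) {
  cols <- attr(ct, "covariate_cols")
  scaling <- attr(ct, "scaling")
  squared <- attr(ct, "squared")
  veg <- stack$layers$veg_class$values
  land <- land_mask(stack)
  n <- length(veg)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (cl in cols) {
    if (startsWith(cl, "patch_")) {
      nm <- sub("^patch_", "", cl)
      X[, cl] <- as.numeric(veg == match(nm, stack$class_names))
    } else if (endsWith(cl, "_sq")) {
      next # filled after its base column
    } else {
      s <- scaling[[cl]]
      X[, cl] <- (as.vector(covariate_layer(stack, cl)) - s["mean"]) / s["sd"]
    }
  }
  for (cl in cols[endsWith(cols, "_sq")]) {
    X[, cl] <- X[, sub("_sq$", "", cl)]^2
  }
  list(X = X, land = as.vector(land) & rowSums(is.na(X)) == 0)
}

#' Relative-probability-of-use surface from a fitted model
#'
#' Maps the fitted model over the landscape with the logistic form
#' `w(x) = exp(b0 + sum_i beta_i x_i) / (1 + exp(b0 + sum_i beta_i x_i))`,
#' where every covariate is transformed and standardized with the training
#' statistics stored on the design table. Water and no-data cells are
#' masked. Patch-scale (conditional logistic) fits have no intercept;
#' `b0 = 0` is used and the surface is interpreted as relative only.
#'
#' @param fit an `rsf_fit`.
#' @param stack the `landscape_stack` (with derived layers for every
#'   covariate in the fit).
#' @param ct the `covariate_table` the model was fitted on (supplies the
#'   stored scaling).
#' @return object of class `prediction_surface`: `w` (raster_grid in
#'   \[0, 1\], `NA` on water), `intercept_used`, `relative_only`.
#' @export
predict_surface <- function(fit, stack, ct) {
  missing_cov <- setdiff(fit$covariates, attr(ct, "covariate_cols"))
  if (length(missing_cov) > 0) {
    stop("covariates missing from the design table: ",
         paste(missing_cov, collapse = ", "))
  }
  dd <- design_for_cells(stack, ct)
  b0 <- if (is.na(fit$intercept)) 0 else fit$intercept
  eta <- b0 + as.vector(dd$X[, fit$covariates, drop = FALSE] %*% fit$beta)
  w <- stats::plogis(eta)
  w[!dd$land] <- NA
  g <- stack$layers$veg_class
  structure(list(
    w = raster_grid(matrix(w, nrow(g$values), ncol(g$values)),
                    g$xmin, g$ymin, g$cellsize),
    intercept_used = b0,
    relative_only = is.na(fit$intercept)
  ), class = "prediction_surface")
}

#' Quantile classification of a prediction surface
#'
#' Cuts the land cells of `w` into `n_classes` equal-quantile classes;
#' class `n_classes` holds the highest relative probabilities. A constant
#' surface collapses to a single class with a warning.
#'
#' @param surface a [predict_surface()] result.
#' @param n_classes number of classes (default 10).
#' @return `raster_grid` of integer classes (`NA` on water).
#' @export
classify_surface <- function(surface, n_classes = 10) {
  w <- surface$w$values
  v <- w[!is.na(w)]
  if (length(unique(v)) == 1) {
    warning("constant surface: single class")
    cl <- w
    cl[!is.na(cl)] <- 1
    return(raster_grid(cl, surface$w$xmin, surface$w$ymin,
                       surface$w$cellsize))
  }
  br <- unique(stats::quantile(v, probs = seq(0, 1,
                                              length.out = n_classes + 1)))
  br[1] <- -Inf; br[length(br)] <- Inf
  cl <- w
  cl[!is.na(w)] <- cut(v, br, labels = FALSE)
  raster_grid(cl, surface$w$xmin, surface$w$ymin, surface$w$cellsize)
}
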