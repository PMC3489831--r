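#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %s, %d coefficients, AIC %.2f\n",
              x$model, length(x$beta), x$aic))
  tab <- data.frame(beta = x$beta, se = x$se_naive)
  if (!is.null(x$se_robust)) tab$se_robust <- x$se_robust
  print(round(tab, 4))
  invisible(x)
}

# within-stratum softmax probabilities
clogit_probs <- function(eta, strata) {
  mx <- stats::ave(eta, strata, FUN = max)
  w <- exp(eta - mx)
  denom <- stats::ave(w, strata, FUN = sum)
  w / denom
}

#' Conditional logistic regression for matched used-available strata
#'
#' Maximizes the conditional log-likelihood
#' `sum_s [beta' x_used - log sum_j exp(beta' x_j)]` over strata each
#' containing exactly one used row, by Newton-Raphson with step halving,
#' iterating until the gradient norm falls below `tol`. The naive
#' covariance is the inverse observed information. This is the patch-scale
#' step-selection estimator; the stratum conditioning removes the
#' intercept.
#'
#' @param table data.frame with a 0/1 `used` column, a `stratum` column,
#'   and the covariate columns.
#' @param covariates covariate column names (default: the
#'   `covariate_cols` attribute left by [build_design()]).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `rsf_fit` (`beta`, `se_naive`, `vcov_naive`,
#'   `loglik`, `aic`, `converged`, `grad_norm`, `refit` closure).
#' @export
fit_conditional_logistic <- function(table,
                                     covariates = attr(table, "covariate_cols"),
                                     tol = 1e-8, max_iter = 50L) {
  stopifnot(!is.null(covariates), all(covariates %in% names(table)))
  X <- as.matrix(table[, covariates, drop = FALSE])
  y <- table$used
  strata <- as.character(table$stratum)
  n_used <- tapply(y, strata, sum)
  if (any(n_used != 1)) stop("every stratum must contain exactly one used row")

  # estimability: a covariate constant within every stratum carries no
  # information; zero-information strata (all covariates constant) warn
  ns <- tabulate(factor(strata))
  sm <- rowsum(X, strata) / as.vector(table(strata))
  ssq <- rowsum(X^2, strata) / as.vector(table(strata))
  wvar <- ssq - sm^2
  col_bad <- colSums(wvar > 1e-12) == 0
  if (any(col_bad)) {
    stop("covariate constant within all strata (inestimable): ",
         paste(covariates[col_bad], collapse = ", "))
  }
  if (any(rowSums(wvar > 1e-12) == 0)) {
    warning(sum(rowSums(wvar > 1e-12) == 0),
            " strata have constant covariates and contribute no information")
  }

  k <- ncol(X)
  b <- numeric(k)
  ll_fun <- function(b) {
    eta <- as.vector(X %*% b)
    mx <- stats::ave(eta, strata, FUN = max)
    w <- exp(eta - mx)
    lse <- log(rowsum(w, strata)) + rowsum(mx, strata) / ns # mx constant per stratum
    sum(eta[y == 1]) - sum(lse)
  }
  ll <- ll_fun(b)
  grad_norm <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- clogit_probs(eta, strata)
    grad <- colSums(X * (y - p))
    A <- crossprod(X, X * p)
    M <- rowsum(X * p, strata)
    H <- A - crossprod(M)                     # negative Hessian
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, k), grad)
    })
    # step halving
    for (h in 0:30) {
      b_new <- b + step / 2^h
      ll_new <- ll_fun(b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    b <- b_new; ll <- ll_new
    if (max(abs(b)) > 50) {
      stop("separation detected: coefficient diverging for ",
           covariates[which.max(abs(b))])
    }
  }
  eta <- as.vector(X %*% b)
  p <- clogit_probs(eta, strata)
  A <- crossprod(X, X * p)
  M <- rowsum(X * p, strata)
  H <- A - crossprod(M)
  vcov <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  dimnames(vcov) <- list(covariates, covariates)
  structure(list(
    model = "conditional_logistic",
    beta = stats::setNames(as.vector(b), covariates),
    se_naive = stats::setNames(sqrt(diag(vcov)), covariates),
    vcov_naive = vcov,
    loglik = ll, aic = -2 * ll + 2 * k, k = k,
    converged = converged, grad_norm = grad_norm,
    covariates = covariates, intercept = NA_real_,
    refit = function(newdata) fit_conditional_logistic(newdata, covariates,
                                                       tol, max_iter)
  ), class = "rsf_fit")
}

#' Random-intercept logistic model for landscape-scale selection
#'
#' Fits a Bernoulli logit GLMM with crossed random intercepts for animal
#' and year (Laplace approximation via lme4); grouping factors with fewer
#' than two levels are dropped from the random part, reducing to ordinary
#' logistic regression when none remain.
#'
#' @param table data.frame with `used`, the covariates, and the grouping
#'   columns.
#' @param covariates covariate column names.
#' @param re_factors random-intercept grouping columns present in `table`.
#' @return `rsf_fit` with `intercept`, fixed-effect `beta`, naive
#'   covariance, AIC, and `re_sd` (named random-intercept SDs).
#' @export
fit_mixed_logistic <- function(table,
                               covariates = attr(table, "covariate_cols"),
                               re_factors = c("animal_id", "year")) {
  stopifnot(!is.null(covariates), all(covariates %in% names(table)))
  re_factors <- re_factors[re_factors %in% names(table)]
  re_factors <- re_factors[vapply(re_factors,
                                  function(f) length(unique(table[[f]])) > 1,
                                  logical(1))]
  bt <- paste0("`", covariates, "`")
  fixed <- paste("used ~", paste(bt, collapse = " + "))
  re_sd <- numeric(0)
  if (length(re_factors) > 0) {
    form <- stats::as.formula(paste(
      fixed, "+", paste(sprintf("(1 | %s)", re_factors), collapse = " + ")))
    mod <- lme4::glmer(form, data = table, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    fe <- lme4::fixef(mod)
    vc <- as.matrix(stats::vcov(mod))
    vcs <- lme4::VarCorr(mod)
    re_sd <- vapply(vcs, function(m) sqrt(m[1, 1]), numeric(1))
    ll <- as.numeric(stats::logLik(mod))
    k <- length(fe) + length(re_sd)
  } else {
    mod <- stats::glm(stats::as.formula(fixed), data = table,
                      family = stats::binomial())
    fe <- stats::coef(mod)
    vc <- as.matrix(stats::vcov(mod))
    ll <- as.numeric(stats::logLik(mod))
    k <- length(fe)
  }
  idx <- setdiff(seq_along(fe), 1L)
  beta <- fe[idx]
  names(beta) <- covariates
  vcov_b <- vc[idx, idx, drop = FALSE]
  dimnames(vcov_b) <- list(covariates, covariates)
  structure(list(
    model = "mixed_logistic",
    beta = beta,
    se_naive = stats::setNames(sqrt(diag(vcov_b)), covariates),
    vcov_naive = vcov_b,
    intercept = unname(fe[1]),
    intercept_se = sqrt(vc[1, 1]),
    re_sd = re_sd,
    loglik = ll, aic = -2 * ll + 2 * k, k = k,
    converged = TRUE, covariates = covariates,
    model_obj = mod,
    refit = function(newdata) fit_mixed_logistic(newdata, covariates,
                                                 re_factors)
  ), class = "rsf_fit")
}

#' All-subsets AIC model selection over covariate blocks
#'
#' Fits every non-empty combination of the supplied covariate blocks
#' (vegetation type enters as a single block of patch dummies) with the
#' given fitter and ranks by AIC, breaking ties toward fewer parameters.
#' Member fits that fail are recorded and excluded with a warning.
#'
#' @param table used-available table.
#' @param blocks named list; each element a character vector of covariate
#'   columns entering or leaving together (<= 20 blocks).
#' @param fitter function(table, covariates) returning an `rsf_fit`.
#' @return list `best_fit`, `best_blocks`, `ranking` (data.frame: model,
#'   aic, k), `failed` (character).
#' @export
all_subsets_aic <- function(table, blocks,
                            fitter = fit_conditional_logistic) {
  stopifnot(length(blocks) >= 1, length(blocks) <= 20,
            !is.null(names(blocks)))
  nb <- length(blocks)
  subsets <- lapply(seq_len(2^nb - 1), function(m) {
    which(bitwAnd(m, 2^(seq_len(nb) - 1)) > 0)
  })
  rows <- list(); fits <- list(); failed <- character(0)
  for (s in subsets) {
    label <- paste(names(blocks)[s], collapse = "+")
    covs <- unlist(blocks[s], use.names = FALSE)
    f <- tryCatch(fitter(table, covs), error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, label)
      next
    }
    fits[[label]] <- f
    rows[[label]] <- data.frame(model = label, aic = f$aic, k = f$k)
  }
  if (length(failed) > 0) {
    warning("model fits failed and were excluded: ",
            paste(failed, collapse = "; "))
  }
  if (length(rows) == 0) stop("no candidate model could be fitted")
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$aic, ranking$k), , drop = FALSE]
  rownames(ranking) <- NULL
  best <- ranking$model[1]
  list(best_fit = fits[[best]],
       best_blocks = strsplit(best, "+", fixed = TRUE)[[1]],
       ranking = ranking, failed = failed)
}

#' Screen continuous covariates for non-linearity
#'
#' For each column, compares single-variable logistic fits (`used ~ x` vs
#' `used ~ x + x^2`) and flags a squared term when the quadratic model
#' improves AIC by more than `delta_aic`. Constant columns are skipped.
#'
#' @param table used-available table.
#' @param columns standardized continuous columns to screen.
#' @param delta_aic AIC improvement needed to add a square term.
#' @return list `squared` (columns to square) and `log` (data.frame with
#'   both AICs per column).
#' @export
quadratic_screen <- function(table, columns, delta_aic = 2) {
  rows <- list(); squared <- character(0)
  for (cl in columns) {
    x <- table[[cl]]
    if (stats::sd(x) == 0) next
    d <- data.frame(used = table$used, x = x)
    a_lin <- stats::AIC(stats::glm(used ~ x, data = d,
                                   family = stats::binomial()))
    fq <- stats::glm(used ~ x + I(x^2), data = d,
                     family = stats::binomial())
    a_quad <- stats::AIC(fq)
    add <- (a_lin - a_quad) > delta_aic
    if (add) squared <- c(squared, cl)
    rows[[cl]] <- data.frame(column = cl, aic_linear = a_lin,
                             aic_quadratic = a_quad, squared = add,
                             quad_sign = sign(stats::coef(fq)[3]))
  }
  list(squared = squared, log = do.call(rbind, rows))
}

# per-row deviance residuals for either fit type
deviance_residuals <- function(fit, table) {
  y <- table$used
  if (fit$model == "conditional_logistic") {
    X <- as.matrix(table[, fit$covariates, drop = FALSE])
    p <- clogit_probs(as.vector(X %*% fit$beta), as.character(table$stratum))
  } else {
    p <- as.vector(stats::fitted(fit$model_obj))
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Residual autocorrelation lag of a fitted selection model
#'
#' Computes deviance residuals, sums them per stratum (per row when the
#' design has no strata), orders the stratum sums in time within each
#' animal, removes the animal-level mean with an intercept-only
#' linear mixed model, and reads the empirical autocorrelation function of
#' each animal's series. The lag is the smallest L at which the ACF enters
#' the +-1.96/sqrt(m) white-noise band; the reported value is the maximum
#' over animals. Animals with fewer than 10 strata contribute lag 1 with a
#' warning.
#'
#' @param fit an `rsf_fit`.
#' @param table the table the model was fitted to (needs `animal_id`,
#'   `timestamp`, and `stratum` for patch-scale fits).
#' @return list `lag` (integer >= 1) and `per_animal` (named lags).
#' @export
residual_lag <- function(fit, table) {
  dr <- deviance_residuals(fit, table)
  if ("stratum" %in% names(table)) {
    agg <- stats::aggregate(
      list(res = dr),
      by = list(stratum = table$stratum, animal_id = table$animal_id,
                time = as.numeric(table$timestamp)),
      FUN = sum)
  } else {
    agg <- data.frame(res = dr, animal_id = table$animal_id,
                      time = as.numeric(table$timestamp))
  }
  agg <- agg[order(agg$animal_id, agg$time), , drop = FALSE]
  if (length(unique(agg$animal_id)) > 1) {
    lmm <- suppressMessages(lme4::lmer(res ~ 1 + (1 | animal_id),
                                       data = agg))
    agg$centered <- stats::residuals(lmm)
  } else {
    agg$centered <- agg$res - mean(agg$res)
  }
  lags <- vapply(split(agg$centered, agg$animal_id), function(r) {
    m <- length(r)
    if (m < 10) return(NA_integer_)
    a <- stats::acf(r, lag.max = min(m - 1, 40), plot = FALSE)$acf[-1]
    band <- 1.96 / sqrt(m)
    inside <- which(abs(a) < band)
    if (length(inside) == 0) return(length(a))
    as.integer(inside[1])
  }, integer(1))
  if (any(is.na(lags))) {
    warning(sum(is.na(lags)), " animals with < 10 strata; lag 1 assumed")
    lags[is.na(lags)] <- 1L
  }
  list(lag = max(lags), per_animal = lags)
}

#' Autocorrelation-robust refit by split-sample covariance averaging
#'
#' Orders the strata (rows, for designs without strata) in time within each
#' animal, assigns alternating blocks of `lag` consecutive strata to two
#' groups so that observations `lag` apart land in different groups, refits
#' the model on each group, and averages the two naive covariance matrices.
#' The square roots of the diagonal are the adjusted (robust) standard
#' errors; a coefficient is flagged significant when the 95% CI
#' `beta +- 1.96 * se_robust` (beta from the full fit) excludes zero. If a
#' group is too small to fit, the naive covariance is kept with a warning.
#'
#' @param fit full-data `rsf_fit` (must carry its `refit` closure).
#' @param table the fitting table.
#' @param lag residual correlation lag from [residual_lag()].
#' @return the fit, augmented with `se_robust`, `vcov_robust`,
#'   `residual_lag`, and `significant` (logical per coefficient).
#' @export
robust_refit <- function(fit, table, lag) {
  stopifnot(lag >= 1)
  if ("stratum" %in% names(table)) {
    units <- unique(data.frame(stratum = table$stratum,
                               animal_id = table$animal_id,
                               time = as.numeric(table$timestamp)))
    units <- units[order(units$animal_id, units$time), , drop = FALSE]
    pos <- stats::ave(seq_len(nrow(units)), units$animal_id, FUN = seq_along)
    units$grp <- ((ceiling(pos / lag) - 1) %% 2) + 1
    grp <- units$grp[match(table$stratum, units$stratum)]
  } else {
    o <- order(table$animal_id, as.numeric(table$timestamp))
    grp <- integer(nrow(table))
    pos <- stats::ave(seq_along(o), table$animal_id[o], FUN = seq_along)
    grp[o] <- ((ceiling(pos / lag) - 1) %% 2) + 1
  }
  v <- tryCatch({
    f1 <- fit$refit(table[grp == 1, , drop = FALSE])
    f2 <- fit$refit(table[grp == 2, , drop = FALSE])
    (f1$vcov_naive + f2$vcov_naive) / 2
  }, error = function(e) {
    warning("split-group refit failed (", conditionMessage(e),
            "); falling back to the naive covariance")
    fit$vcov_naive
  })
  fit$vcov_robust <- v
  fit$se_robust <- sqrt(diag(v))
  fit$residual_lag <- lag
  fit$significant <- abs(fit$beta) - 1.96 * fit$se_robust > 0
  fit
}
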