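# Lasso estimation on the residualized standardized design.
#
# The objective is (1/2n) ||yr - Xr beta||^2 + lambda ||beta||_1, where Xr and
# yr are the taxon block and outcome after projecting out the (unpenalized)
# covariates and intercept. Coordinate descent is delegated to glmnet with a
# tight convergence threshold; lambda = 0 is solved exactly by least squares.

lambda_max <- function(xr, yr) {
  max(abs(crossprod(xr, yr))) / nrow(xr)
}

# glmnet solution at an exact lambda: fit a short geometric path ending at the
# target so the warm starts land exactly on it
glmnet_at <- function(x, y, lambda, thresh = 1e-12) {
  lmax <- lambda_max(x, y)
  if (lambda >= lmax) {
    return(setNames(rep(0, ncol(x)), colnames(x)))
  }
  path <- exp(seq(log(lmax), log(lambda), length.out = 25))
  path[length(path)] <- lambda
  fit <- glmnet::glmnet(x, y, family = "gaussian", lambda = path,
                        standardize = FALSE, intercept = FALSE,
                        thresh = thresh, maxit = 1e7)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  setNames(beta, colnames(x))
}

#' Fit the Lasso at a given penalty
#'
#' Minimizes `(1/2n) ||yr - Xr b||^2 + lambda ||b||_1` on the
#' covariate-residualized design; covariates are therefore effectively
#' unpenalized. At `lambda = 0` (requires p < n - q) the exact least-squares
#' solution is returned.
#'
#' @param design A `dab_design` from [standardize_design()].
#' @param lambda Non-negative penalty.
#' @return A `lasso_fit`: coefficient vector `beta`, `lambda`, `residuals`
#'   (on the residualized scale), support size `s_hat`, and dimensions.
#' @export
fit_lasso <- function(design, lambda) {
  stopifnot(inherits(design, "dab_design"), lambda >= 0)
  xr <- design$Xr; yr <- design$yr
  if (lambda == 0) {
    if (design$p >= design$n - design$q) {
      abort("lambda = 0 requires p < n - q (full-rank least squares)")
    }
    beta <- setNames(qr.coef(qr(xr), yr), colnames(xr))
  } else {
    beta <- glmnet_at(xr, yr, lambda)
  }
  r <- yr - drop(xr %*% beta)
  structure(list(beta = beta, lambda = lambda, residuals = r,
                 s_hat = sum(beta != 0), n = design$n, p = design$p,
                 q = design$q),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %.4g, support %d of %d taxa (n = %d)\n",
              x$lambda, x$s_hat, x$p, x$n))
  invisible(x)
}

#' Choose the Lasso penalty by k-fold cross-validation
#'
#' The grid is 100 log-spaced points spanning three decades below the
#' smallest penalty that zeroes every coefficient; folds are a seeded random
#' partition; the returned penalty minimizes mean held-out squared error.
#'
#' @param design A `dab_design`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold partition.
#' @param n_lambda Grid size (default 100).
#' @return A `cv_lasso` list: `lambda` (the minimizer), `grid`, `cvm`, `cvsd`
#'   and the fold assignment.
#' @export
choose_lambda <- function(design, n_folds = 5, seed = 1, n_lambda = 100) {
  stopifnot(inherits(design, "dab_design"))
  xr <- design$Xr; yr <- design$yr
  n <- nrow(xr)
  if (n < n_folds) abort("need n >= n_folds")
  foldid <- make_folds(n, n_folds, derive_seed(seed, 505))
  for (k in seq_len(n_folds)) {
    if (sd(yr[foldid == k]) == 0) {
      warn("degenerate (constant-outcome) fold; resampling the partition")
      foldid <- make_folds(n, n_folds, derive_seed(seed, 515))
      break
    }
  }
  lmax <- lambda_max(xr, yr)
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
  cv <- glmnet::cv.glmnet(xr, yr, lambda = grid, foldid = foldid,
                          family = "gaussian", standardize = FALSE,
                          intercept = FALSE, thresh = 1e-8)
  i <- match(cv$lambda.min, cv$lambda)
  structure(list(lambda = cv$lambda.min, grid = cv$lambda, cvm = cv$cvm,
                 cvsd = cv$cvsd, index = i, foldid = foldid,
                 n_folds = n_folds, seed = seed),
            class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(sprintf("<cv_lasso> %d-fold CV over %d penalties; lambda.min = %.4g\n",
              x$n_folds, length(x$grid), x$lambda))
  invisible(x)
}
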