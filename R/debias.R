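# Desparsified (debiased) Lasso inference.
#
# The Lasso point estimate is biased by shrinkage and has no tractable
# distribution. The desparsified estimator corrects it with an approximate
# inverse covariance Theta built from nodewise Lasso regressions:
#
#   b = beta_hat + Theta t(X) (y - X beta_hat) / n
#
# Each b_j is asymptotically normal, so every taxon gets a coefficient,
# standard error and p-value while controlling for all other taxa and the
# covariates.

#' Nodewise Lasso estimate of the precision matrix
#'
#' For each column j, the Lasso regression of `x_j` on all other columns gives
#' coefficients `gamma_j` and the scale `tau_j^2 = x_j'(x_j - X_{-j}
#' gamma_j)/n`; row j of Theta is `(1, -gamma_j)/tau_j^2` in the appropriate
#' positions. At `lambda = 0` (p < n) this reproduces the exact inverse of
#' the sample covariance.
#'
#' Compositional predictors (within-sample relative abundances) carry an
#' exact sum-to-one dependency, so an unconstrained nodewise regression could
#' fit each column perfectly and collapse `tau_j^2` to zero. The
#' cross-validation grid is therefore floored at `lambda_min_ratio` times each
#' column's own lambda-max, which keeps the nodewise scales bounded away from
#' the singular limit.
#'
#' @param x Standardized predictor matrix (typically `design$Xr`).
#' @param lambda `"cv"` for per-column fivefold cross-validation (default),
#'   `"shared-cv"` to cross-validate a subset of `n_shared` columns and apply
#'   the median penalty to all (much faster at large p), a numeric scalar or
#'   length-p vector, or 0 for the exact inverse.
#' @param n_folds Folds for cross-validation.
#' @param seed Integer seed for fold partitions and the shared-column sample.
#' @param n_shared Number of columns cross-validated under `"shared-cv"`.
#' @param lambda_min_ratio Lower end of each column's cross-validation grid,
#'   as a fraction of that column's lambda-max (default 0.05).
#' @return A `nodewise_fit`: `Theta` (p x p), `tau2` (length p), and the
#'   per-column penalties used.
#' @export
nodewise_theta <- function(x, lambda = "cv", n_folds = 5, seed = 1,
                           n_shared = 10, lambda_min_ratio = 0.05) {
  n <- nrow(x); p <- ncol(x)
  taxa <- colnames(x) %||% paste0("V", seq_len(p))

  if (is.numeric(lambda) && length(lambda) == 1 && lambda == 0) {
    sigma <- crossprod(x) / n
    theta <- tryCatch(solve(sigma), error = function(e) {
      abort("sample covariance is singular; lambda = 0 needs p < n")
    })
    tau2 <- 1 / diag(theta)
    dimnames(theta) <- list(taxa, taxa)
    return(structure(list(Theta = theta, tau2 = setNames(tau2, taxa),
                          lambda = setNames(rep(0, p), taxa),
                          method = "exact-inverse"),
                     class = "nodewise_fit"))
  }

  foldid <- make_folds(n, n_folds, derive_seed(seed, 606))
  node_grid <- function(xm, xj) {
    lmax <- lambda_max(xm, xj)
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = 30))
  }
  node_cv <- function(j) {
    xm <- x[, -j, drop = FALSE]
    cv <- glmnet::cv.glmnet(xm, x[, j], lambda = node_grid(xm, x[, j]),
                            foldid = foldid, family = "gaussian",
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-8)
    cv$lambda.min
  }
  lam <- numeric(p)
  method <- "fixed"
  if (identical(lambda, "cv")) {
    method <- "cv"
  } else if (identical(lambda, "shared-cv")) {
    method <- "shared-cv"
    cols <- withr::with_seed(derive_seed(seed, 616),
                             sample(p, min(n_shared, p)))
    lam[] <- median(vapply(cols, node_cv, numeric(1)))
  } else if (is.numeric(lambda)) {
    lam[] <- lambda
  } else {
    abort("lambda must be 'cv', 'shared-cv', or numeric")
  }

  theta <- matrix(0, p, p, dimnames = list(taxa, taxa))
  tau2 <- numeric(p)
  lam_used <- numeric(p)
  for (j in seq_len(p)) {
    xj <- x[, j]
    xm <- x[, -j, drop = FALSE]
    if (method == "cv") {
      lam_used[j] <- node_cv(j)
      gamma <- glmnet_at(xm, xj, lam_used[j], thresh = 1e-9)
    } else {
      lam_used[j] <- lam[j]
      gamma <- glmnet_at(xm, xj, lam[j], thresh = 1e-9)
    }
    rj <- xj - drop(xm %*% gamma)
    tau2[j] <- sum(xj * rj) / n
    if (tau2[j] < 1e-12) {
      abort(sprintf("nodewise scale collapsed for taxon '%s' (collinearity)",
                    taxa[j]))
    }
    theta[j, j] <- 1 / tau2[j]
    theta[j, -j] <- -gamma / tau2[j]
  }
  structure(list(Theta = theta, tau2 = setNames(tau2, taxa),
                 lambda = setNames(lam_used, taxa), method = method),
            class = "nodewise_fit")
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat(sprintf("<nodewise_fit> p = %d, method = %s, tau2 in [%.3g, %.3g]\n",
              length(x$tau2), x$method, min(x$tau2), max(x$tau2)))
  invisible(x)
}

#' Debiased coefficients, standard errors and p-values
#'
#' Applies the desparsification correction to a Lasso fit and tests each
#' coefficient. The noise SD is estimated from the Lasso residuals with a
#' degrees-of-freedom correction `n - s_hat - q` (support size plus covariate
#' terms); standard errors are `sigma_hat * sqrt((Theta Sigma Theta')_jj / n)`
#' with `Sigma = X'X/n`, and p-values are two-sided normal. In the
#' least-squares limit (lambda = 0, Theta the exact inverse) the result
#' reproduces classical OLS estimates and standard errors.
#'
#' @param fit A `lasso_fit` on the same design.
#' @param nodewise A `nodewise_fit` on `design$Xr`.
#' @param design The `dab_design` both were computed from.
#' @return A tibble with one row per taxon: `taxon_id`, `coefficient`
#'   (debiased, on the standardized scale), `se`, `z`, `p_value`,
#'   `significant` (p < 0.05). `sigma_hat` and the degrees of freedom are
#'   attached as attributes.
#' @export
debias_lasso <- function(fit, nodewise, design) {
  stopifnot(inherits(fit, "lasso_fit"), inherits(nodewise, "nodewise_fit"),
            inherits(design, "dab_design"))
  xr <- design$Xr
  n <- design$n
  theta <- nodewise$Theta
  if (!identical(colnames(xr), colnames(theta))) {
    abort("nodewise fit and design disagree on taxa")
  }
  df <- n - fit$s_hat - design$q
  if (df <= 0) {
    abort("non-positive residual degrees of freedom; increase n or the penalty")
  }
  sigma_hat <- sqrt(sum(fit$residuals^2) / df)

  b <- fit$beta + drop(theta %*% crossprod(xr, fit$residuals)) / n
  sigma_x <- crossprod(xr) / n
  omega <- theta %*% sigma_x %*% t(theta)
  se <- sigma_hat * sqrt(diag(omega) / n)
  z <- b / se
  p <- 2 * pnorm(-abs(z))

  out <- tibble(taxon_id = colnames(xr), coefficient = unname(b),
                se = unname(se), z = unname(z), p_value = unname(p),
                significant = unname(p) < 0.05)
  attr(out, "sigma_hat") <- sigma_hat
  attr(out, "df") <- df
  out
}
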