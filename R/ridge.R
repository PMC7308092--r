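#' Ridge-regression specification
#'
#' The penalty grid defaults to 100 log-spaced values between 1e-3 and 1e5;
#' the penalty is selected by generalized cross-validation (GCV).
#'
#' @param lambda_grid Strictly increasing penalty grid.
#' @return A `ridge_spec` list.
#' @export
ridge_spec <- function(lambda_grid = 10^seq(-3, 5, length.out = 100)) {
  if (any(diff(lambda_grid) <= 0)) abort("`lambda_grid` must be increasing.")
  structure(list(lambda_grid = lambda_grid), class = "ridge_spec")
}

#' Fit ridge regression with GCV-selected penalty
#'
#' Solves `beta = (X'X + lambda I)^-1 X'y` on internally standardized
#' predictors (training mean/SD), with the whole regularization path
#' evaluated through a single SVD. The penalty minimizing the GCV
#' criterion `n * RSS / (n - df)^2`, with `df = 1 + sum(d^2 / (d^2 +
#' lambda))` (intercept plus shrunk directions), is selected.
#'
#' @param x Samples x features matrix without missing values.
#' @param y Numeric target (years).
#' @param spec A [ridge_spec()].
#' @return A `ridge_model` with coefficients on the original scale, the
#'   selected `lambda`, and the full `gcv_path` tibble.
#' @export
fit_ridge_gcv <- function(x, y, spec = ridge_spec()) {
  x <- as.matrix(x)
  if (!ncol(x)) abort("`x` must have at least one column.")
  if (anyNA(x) || anyNA(y)) abort("missing values in `x` or `y`.")
  n <- nrow(x)
  if (n != length(y)) abort("`x` rows and `y` length differ.")
  if (sd(y) == 0) abort("degenerate target: `y` is constant.")

  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  keep <- scale_ > 0
  if (!any(keep)) abort("all predictors are constant.")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, center[keep]),
              2L, scale_[keep], `/`)
  ybar <- mean(y)
  yc <- y - ybar

  sv <- svd(xs)
  uty <- crossprod(sv$u, yc)
  d2 <- sv$d^2

  path <- vapply(spec$lambda_grid, function(lam) {
    shrink <- d2 / (d2 + lam)
    fitted <- sv$u %*% (shrink * uty)
    df <- 1 + sum(shrink)
    rss <- sum((yc - fitted)^2)
    c(gcv = n * rss / (n - df)^2, df = df)
  }, numeric(2))
  best <- which.min(path["gcv", ])
  lambda <- spec$lambda_grid[best]

  beta_s <- sv$v %*% ((sv$d / (d2 + lambda)) * uty)
  beta <- numeric(ncol(x))
  beta[keep] <- beta_s / scale_[keep]
  intercept <- ybar - sum(center[keep] * beta[keep])

  structure(list(
    coefficients = setNames(beta, colnames(x)),
    intercept = intercept, lambda = lambda,
    gcv_path = tibble(lambda = spec$lambda_grid,
                      gcv = path["gcv", ], df = path["df", ]),
    center = center, scale = scale_, keep = keep, n = n, p = ncol(x)),
    class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> p = %d, n = %d, lambda = %.4g (GCV)\n",
              x$p, x$n, x$lambda))
  invisible(x)
}

#' @export
tidy.ridge_model <- function(x, ...) {
  tibble(term = names(x$coefficients) %||%
           sprintf("x%d", seq_along(x$coefficients)),
         estimate = unname(x$coefficients))
}

#' @export
glance.ridge_model <- function(x, ...) {
  i <- which(x$gcv_path$lambda == x$lambda)
  tibble(lambda = x$lambda, gcv = x$gcv_path$gcv[i],
         df = x$gcv_path$df[i], n = x$n, p = x$p)
}
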