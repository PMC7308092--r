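#' OAS-shrunk covariance
#'
#' James-Stein-type shrinkage of the empirical covariance toward a scaled
#' identity, `(1 - alpha) * S + alpha * (tr(S)/p) * I`, with the shrinkage
#' weight `alpha` given by the closed-form Oracle Approximating Shrinkage
#' estimator (Chen et al. 2010), clipped to `[0, 1]`. The empirical
#' covariance uses the maximum-likelihood `1/n` normalization after column
#' centering.
#'
#' @param x Samples x features data matrix (at least 2 rows).
#' @param alpha Optional forced shrinkage weight in `[0, 1]`; by default the
#'   OAS value is used.
#' @return List with `sigma` (the shrunk covariance), `alpha` and the
#'   empirical covariance `sample` (for inspection).
#' @export
oas_shrunk_covariance <- function(x, alpha = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) abort("at least 2 samples are required.")
  xc <- sweep(x, 2L, colMeans(x))
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  if (mu <= 0) abort("constant data: covariance trace is zero.")
  if (is.null(alpha)) {
    tr_s2 <- sum(s^2)
    tr_s <- sum(diag(s))
    num <- (1 - 2 / p) * tr_s2 + tr_s^2
    den <- (n + 1 - 2 / p) * (tr_s2 - tr_s^2 / p)
    alpha <- if (den <= 0) 1 else min(1, num / den)
    alpha <- max(0, alpha)
  }
  sigma <- (1 - alpha) * s + alpha * mu * diag(p)
  list(sigma = sigma, alpha = alpha, sample = s)
}

geometric_mean_spd <- function(covs, tol = 1e-8, max_iter = 50L) {
  ref <- Reduce(`+`, covs) / length(covs)
  for (it in seq_len(max_iter)) {
    isq <- powm_spd(ref, -0.5, "reference")
    sq <- powm_spd(ref, 0.5, "reference")
    w <- Reduce(`+`, lapply(covs, function(c_i) {
      logm_spd(isq %*% c_i %*% isq, "input covariance")
    })) / length(covs)
    ref <- sym_part(sq %*% expm_sym(w) %*% sq)
    if (sqrt(sum(w^2)) < tol) return(ref)
  }
  warn("geometric mean did not converge; falling back to the log-Euclidean mean.")
  expm_sym(Reduce(`+`, lapply(covs, logm_spd)) / length(covs))
}

#' Tangent-space projection of covariance matrices
#'
#' Maps positive-definite matrices to Euclidean vectors via the matrix
#' logarithm at a reference point:
#' `S_i = logm(R^(-1/2) C_i R^(-1/2))`. The diagonal of `S_i` serves as
#' log-variance "power" features; the strict lower triangle, scaled by
#' `sqrt(2)` (isometric convention), serves as connectivity features.
#'
#' @param covs List of p x p covariance matrices (or a single matrix).
#' @param reference `"geometric_mean"` (affine-invariant Frechet mean by
#'   fixed-point iteration) or an explicit p x p reference matrix.
#' @return List of `tangent_vector` objects, each with `diag_part`
#'   (length p) and `offdiag_part` (length p(p-1)/2).
#' @export
tangent_space <- function(covs, reference = "geometric_mean") {
  if (is.matrix(covs)) covs <- list(covs)
  p <- nrow(covs[[1L]])
  for (i in seq_along(covs)) {
    if (!isTRUE(all.equal(covs[[i]], t(covs[[i]]), tolerance = 1e-8))) {
      abort(sprintf("matrix %d is not symmetric.", i))
    }
    ev <- eigen(sym_part(covs[[i]]), symmetric = TRUE, only.values = TRUE)
    if (min(ev$values) <= 1e-10 * max(abs(ev$values))) {
      abort(sprintf("matrix %d is not positive definite.", i))
    }
  }
  ref <- if (is.character(reference) && reference == "geometric_mean") {
    geometric_mean_spd(covs)
  } else {
    reference
  }
  isq <- powm_spd(ref, -0.5, "reference")
  lower <- lower.tri(matrix(0, p, p))
  lapply(covs, function(c_i) {
    s <- logm_spd(isq %*% c_i %*% isq, "whitened covariance")
    structure(list(diag_part = diag(s),
                   offdiag_part = s[lower] * sqrt(2),
                   reference = ref),
              class = "tangent_vector")
  })
}

#' Inverse tangent-space map
#'
#' Reconstructs the covariance `C = R^(1/2) expm(S) R^(1/2)` from a tangent
#' vector, inverting [tangent_space()].
#'
#' @param tv A `tangent_vector`.
#' @param reference Reference matrix; defaults to the one stored in `tv`.
#' @return The reconstructed covariance matrix.
#' @export
tangent_space_inverse <- function(tv, reference = NULL) {
  ref <- reference %||% tv$reference
  p <- length(tv$diag_part)
  s <- matrix(0, p, p)
  s[lower.tri(s)] <- tv$offdiag_part / sqrt(2)
  s <- s + t(s)
  diag(s) <- tv$diag_part
  sq <- powm_spd(ref, 0.5, "reference")
  sym_part(sq %*% expm_sym(s) %*% sq)
}

#' Connectivity values of a tangent vector
#'
#' The off-diagonal tangent entries serve as connectivity features; their
#' number is `p(p-1)/2` (100,128 at p = 448, 32,640 at p = 256).
#'
#' @param tv A `tangent_vector` from [tangent_space()].
#' @return Numeric vector of length `p(p-1)/2`.
#' @export
connectivity_values <- function(tv) {
  stopifnot(inherits(tv, "tangent_vector"))
  tv$offdiag_part
}

#' Fisher z-transform
#'
#' `z = arctanh(r) = log((1 + r) / (1 - r)) / 2`, applied element-wise.
#' Used for (orthogonalized) correlation matrices that are no longer
#' positive definite and hence cannot go through the tangent projection.
#'
#' @param r Correlations with `|r| < 1`.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) abort("|r| must be < 1 for the Fisher z-transform.")
  0.5 * log((1 + r) / (1 - r))
}

#' Envelope correlation, optionally orthogonalized
#'
#' Computes Pearson correlations between Hilbert amplitude envelopes. With
#' `orthogonalize = TRUE`, for each ordered channel pair the zero-lag
#' component of one raw signal is regressed out of the other before the
#' envelope is taken, and the two directions are averaged (a time-domain
#' member of the orthogonalization family used to mitigate source leakage).
#' Identical signals therefore yield an orthogonalized correlation of 0.
#'
#' @param signal A `multichannel_signal` or channels x samples matrix of raw
#'   band-limited signals.
#' @param orthogonalize Remove the shared zero-lag component first?
#' @return Channels x channels correlation matrix. Zero-variance channels
#'   produce `NA` entries with a warning.
#' @export
envelope_correlation <- function(signal, orthogonalize = FALSE) {
  x <- if (inherits(signal, "multichannel_signal")) signal$data else
    rbind(signal)
  if (ncol(x) < 2L) abort("at least 2 samples are required.")
  p <- nrow(x)
  vars <- apply(x, 1L, var)
  if (any(vars <= 0)) warn("zero-variance channel(s): entries flagged NA.")
  env <- hilbert_envelope(x)$data
  out <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      if (vars[i] <= 0 || vars[j] <= 0) {
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      if (!orthogonalize) {
        out[i, j] <- out[j, i] <- cor(env[i, ], env[j, ])
      } else {
        r_ij <- orth_env_cor(x[i, ], x[j, ], env[i, ])
        r_ji <- orth_env_cor(x[j, ], x[i, ], env[j, ])
        out[i, j] <- out[j, i] <- (r_ij + r_ji) / 2
      }
    }
  }
  out
}

# correlation of env(xi) with the envelope of xj after removing the
# zero-lag component of xi; 0 when the residual is degenerate
orth_env_cor <- function(xi, xj, env_i) {
  resid <- xj - sum(xi * xj) / sum(xi * xi) * xi
  if (var(resid) < 1e-12 * var(xj) || var(resid) == 0) return(0)
  env_r <- as.numeric(hilbert_envelope(matrix(resid, nrow = 1L))$data)
  if (sd(env_r) == 0 || sd(env_i) == 0) return(0)
  cor(env_i, env_r)
}

#' Minimum-norm inverse operator
#'
#' Returns `W = G' (G G' + lambda I)^-1` for a sensors x sources gain
#' (leadfield) matrix `G`; applying `W` to sensor data yields source
#' estimates. This is the classical L2 minimum-norm operator, a ridge
#' regression from leadfields to fields.
#'
#' @param G P sensors x Q sources gain matrix with finite entries.
#' @param lam Regularization parameter, `> 0`.
#' @return Q x P operator matrix.
#' @export
minimum_norm_operator <- function(G, lam) {
  if (!all(is.finite(G))) abort("`G` must have finite entries.")
  if (lam <= 0) abort("`lam` must be > 0.")
  p <- nrow(G)
  t(G) %*% solve(G %*% t(G) + lam * diag(p))
}
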