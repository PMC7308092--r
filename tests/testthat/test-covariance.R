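test_that("OAS shrinkage hits its closed form and its limits", {
  set.seed(2)
  x <- matrix(rnorm(200 * 4), 200)
  n <- nrow(x)
  p <- ncol(x)

  # forced limits of the convex combination
  emp <- oas_shrunk_covariance(x, alpha = 0)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(emp$sigma, crossprod(xc) / n, tolerance = 1e-12)
  iso <- oas_shrunk_covariance(x, alpha = 1)
  expect_equal(iso$sigma, sum(diag(emp$sigma)) / p * diag(p),
               tolerance = 1e-12)

  # alpha equals an independent hand-coded evaluation of the OAS formula
  fit <- oas_shrunk_covariance(x)
  s <- crossprod(xc) / n
  num <- (1 - 2 / p) * sum(s * s) + sum(diag(s))^2
  den <- (n + 1 - 2 / p) * (sum(s * s) - sum(diag(s))^2 / p)
  expect_equal(fit$alpha, min(1, num / den), tolerance = 1e-12)

  # trace is preserved for every alpha (convex combination)
  for (a in c(0, 0.3, 0.7, 1)) {
    expect_equal(sum(diag(oas_shrunk_covariance(x, alpha = a)$sigma)),
                 sum(diag(s)), tolerance = 1e-10)
  }

  # shrinkage moves a high-dimensional estimate toward the truth
  set.seed(3)
  xx <- matrix(rnorm(30 * 10), 30)
  shr <- oas_shrunk_covariance(xx)
  d_shr <- norm(shr$sigma - diag(10), "F")
  d_emp <- norm(shr$sample - diag(10), "F")
  expect_lt(d_shr, d_emp)

  expect_error(oas_shrunk_covariance(matrix(1, 5, 3)), "constant")
})

test_that("tangent space projection has the stated geometry", {
  set.seed(4)
  # C = R -> zero tangent vector
  r <- random_spd(4)
  tv <- tangent_space(list(r), reference = r)[[1]]
  expect_lt(max(abs(c(tv$diag_part, tv$offdiag_part))), 1e-8)

  # diagonal case: analytic matrix log
  tv2 <- tangent_space(list(diag(c(exp(2), 1))), reference = diag(2))[[1]]
  expect_equal(tv2$diag_part, c(2, 0), tolerance = 1e-10)
  expect_equal(tv2$offdiag_part, 0, tolerance = 1e-10)

  # congruence invariance of pairwise distances
  covs <- lapply(1:4, function(i) random_spd(3))
  ref <- random_spd(3)
  a <- matrix(rnorm(9), 3)
  covs_t <- lapply(covs, function(cc) a %*% cc %*% t(a))
  ref_t <- a %*% ref %*% t(a)
  v1 <- sapply(tangent_space(covs, ref),
               function(t_) c(t_$diag_part, t_$offdiag_part))
  v2 <- sapply(tangent_space(covs_t, ref_t),
               function(t_) c(t_$diag_part, t_$offdiag_part))
  d1 <- dist(t(v1))
  d2 <- dist(t(v2))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)

  # round-trip through the inverse map
  tvs <- tangent_space(covs)
  for (i in seq_along(covs)) {
    expect_equal(tangent_space_inverse(tvs[[i]]), covs[[i]],
                 tolerance = 1e-8)
  }

  # non-PD input names the offender
  bad <- diag(c(1, -1, 1))
  expect_error(tangent_space(list(random_spd(3), bad)),
               "matrix 2")
})

test_that("connectivity feature counts follow p(p-1)/2", {
  # the two headline dimensionalities
  for (p in c(448L, 256L)) {
    tv <- structure(list(diag_part = numeric(p),
                         offdiag_part = numeric(p * (p - 1L) / 2L)),
                    class = "tangent_vector")
    expect_length(connectivity_values(tv), p * (p - 1L) / 2L)
  }
  # property over a range of sizes, via the actual projection
  set.seed(5)
  for (p in c(2L, 5L, 17L, 64L)) {
    tv <- tangent_space(list(random_spd(p)), reference = diag(p))[[1]]
    expect_length(connectivity_values(tv), p * (p - 1L) / 2L)
    expect_length(tv$diag_part, p)
  }
})

test_that("fisher_z matches its formula and inverse", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-14)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  z <- seq(-4.5, 4.5, by = 0.5)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-10)
  expect_error(fisher_z(1), "< 1")
})

test_that("envelope correlation recovers construction and kills leakage", {
  fs <- 100
  t <- seq_len(fs * 60) / fs
  set.seed(6)
  # identical signals, orthogonalized -> 0
  x <- rbind(sin(2 * pi * 10 * t) * (1 + 0.3 * sin(2 * pi * 0.4 * t)))
  xx <- rbind(x, x)
  orth <- envelope_correlation(xx, orthogonalize = TRUE)
  expect_equal(orth[1, 2], 0)

  # independent signals: small plain correlation at 10^4 samples
  y <- rbind(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(envelope_correlation(y)[1, 2]), 0.1)

  # generator coupling 0.7 recovered within +/- 0.1 (strong alpha SNR)
  sig <- simulate_oscillatory(oscillatory_spec(
    n_channels = 2, fs = 200, duration = 120, one_over_f_exponent = 1,
    alpha_peak_hz = 10, alpha_power = 16, envelope_coupling = 0.7,
    seed = 7))
  expect_lt(abs(envelope_correlation(sig)[1, 2] - 0.7), 0.1)
})

test_that("minimum-norm operator solves the regularized system", {
  # G = I, lam -> 0: operator -> I
  w <- minimum_norm_operator(diag(4), 1e-10)
  expect_equal(w, diag(4), tolerance = 1e-8)

  # lam -> infinity: entries scale as 1/lambda
  set.seed(8)
  g <- matrix(rnorm(40), 5, 8)
  w_big <- minimum_norm_operator(g, 1e8)
  expect_lt(max(abs(w_big)), 1e-6)
  expect_equal(w_big * 1e8, t(g), tolerance = 1e-4)

  # independent linear-solve oracle, column by column
  lam <- 1
  w1 <- minimum_norm_operator(g, lam)
  a <- g %*% t(g) + lam * diag(5)
  oracle <- sapply(seq_len(5), function(j) {
    solve(a, diag(5)[, j])
  })
  expect_equal(w1, t(g) %*% oracle, tolerance = 1e-10)

  expect_error(minimum_norm_operator(matrix(c(1, NA), 1), 1), "finite")
  expect_error(minimum_norm_operator(g, 0), "lam")
})
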