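test_that("mae and the dummy baseline match hand arithmetic", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(25, 35), c(20, 40)), 5)
  set.seed(1)
  p <- rnorm(50)
  y <- rnorm(50)
  loop <- 0
  for (i in 1:50) loop <- loop + abs(p[i] - y[i])
  expect_equal(mae(p, y), loop / 50, tolerance = 1e-14)
  expect_error(mae(numeric(), numeric()), "empty")

  expect_equal(dummy_baseline(c(20, 40, 60), c(1, 2)), c(40, 40))
  expect_equal(mae(dummy_baseline(c(20, 40, 60), c(40, 60)), c(40, 60)), 10)
  expect_equal(dummy_baseline(rep(7, 3), 1:5), rep(7, 5))

  # uniform ages on [18, 88]: dummy MAE converges to range/4 = 17.5
  set.seed(2)
  y <- runif(2e4, 18, 88)
  cvb <- cv_scheme(length(y), n_folds = 2, n_repeats = 1, seed = 2)
  expect_lt(abs(mean(dummy_fold_scores(y, cvb)$mae) - 17.5), 0.5)
})

test_that("paired comparisons summarize split-wise differences", {
  cv <- cv_scheme(40, n_folds = 4, n_repeats = 2, seed = 5)
  base <- dummy_fold_scores(rnorm(40, 50, 10), cv)

  # a model against itself: identically zero, strict Pr<Ref = 0
  self <- paired_compare(base, base)
  expect_equal(self$mean_diff, 0)
  expect_equal(self$pr_better, 0)
  expect_equal(c(self$p2.5, self$p97.5), c(0, 0))

  # uniformly better by one year
  better <- base
  better$mae <- base$mae - 1
  cmp <- paired_compare(better, base)
  expect_equal(cmp$mean_diff, -1)
  expect_equal(cmp$pr_better, 1)

  # antisymmetry and a sorted-array percentile oracle
  set.seed(6)
  other <- base
  other$mae <- base$mae + rnorm(8)
  ab <- paired_compare(other, base)
  ba <- paired_compare(base, other)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  d <- sort(other$mae - base$mae)
  expect_equal(ab$p2.5, unname(quantile(d, 0.025)))
  expect_equal(ab$p97.5, unname(quantile(d, 0.975)))

  # misaligned schemes are rejected
  cv2 <- cv_scheme(40, n_folds = 4, n_repeats = 2, seed = 99)
  expect_error(paired_compare(base, dummy_fold_scores(rnorm(40), cv2)),
               "different CV")
})

test_that("rank statistics count wins and handle ties by average rank", {
  cv <- cv_scheme(30, n_folds = 3, n_repeats = 2, seed = 7)
  y <- rnorm(30, 50, 15)
  a <- dummy_fold_scores(y, cv)
  b <- a
  b$mae <- a$mae - 2  # strictly better on every split
  c_ <- a
  set.seed(8)
  c_$mae <- a$mae + rnorm(6, sd = 0.1)

  rk <- rank_models(list(best = b, dummy = a, wiggle = c_))
  expect_equal(sum(rk$rank_freq$freq[rk$rank_freq$model == "best" &
                                       rk$rank_freq$rank == 1]),
               rk$n_splits)
  # pairwise win fractions match a brute-force split loop
  wins <- mean(b$mae < c_$mae)
  expect_equal(rk$pairwise["best", "wiggle"], wins)

  # two identical models: all tied at rank 1.5
  rk2 <- rank_models(list(m1 = a, m2 = a))
  expect_true(all(rk2$ranks == 1.5))
})

test_that("permutation importance matches a fixed-stream oracle", {
  set.seed(9)
  x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "only"))
  y <- drop(x) * 2 + rnorm(200, sd = 0.1)
  set.seed(1)
  fit <- rf_fit(x, y, n_trees = 20)

  k <- 5
  imp <- permutation_importance(fit, x, y, k = k, seed = 77)
  base <- mae(predict(fit, x), y)
  oracle <- mean(sapply(seq_len(k), function(i) {
    xp <- x
    xp[, 1] <- xp[permutation_stream(77, 1L, i, nrow(x)), 1]
    mae(predict(fit, xp), y) - base
  }))
  expect_equal(imp$importance, oracle, tolerance = 1e-12)

  # a constant column the model cannot use has importance 0
  x2 <- cbind(x, constant = 1)
  set.seed(1)
  fit2 <- rf_fit(x2, y, n_trees = 20)
  imp2 <- permutation_importance(fit2, x2, y, k = 3, seed = 1)
  expect_equal(imp2$importance[imp2$feature == "constant"], 0)

  # informative beats noise in a two-feature forest (over seeds)
  hits <- sapply(1:10, function(seed) {
    set.seed(seed)
    xx <- cbind(signal = rnorm(150), noise = rnorm(150))
    yy <- xx[, 1] + rnorm(150, sd = 0.3)
    fit3 <- rf_fit(xx, yy, n_trees = 50)
    im <- permutation_importance(fit3, xx, yy, k = 10, seed = seed)
    im$importance[im$feature == "signal"] >
      im$importance[im$feature == "noise"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("MDI importance normalizes and ignores unused features", {
  set.seed(10)
  x <- cbind(signal = rnorm(150), constant = rep(1, 150))
  y <- x[, 1] * 3 + rnorm(150, sd = 0.2)
  fit <- rf_fit(x, y, n_trees = 30, mtry = 2)
  imp <- mdi_importance(fit)
  expect_equal(sum(imp$importance), 1)
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  expect_equal(imp$importance[imp$feature == "signal"], 1)
  expect_true(all(imp$importance >= 0))
})

test_that("partial dependence reflects model structure", {
  set.seed(11)
  x <- cbind(a = runif(300, -1, 1), b = runif(300, -1, 1))
  y <- 2 * x[, "a"] + 3 * x[, "b"] + rnorm(300, sd = 0.1)
  set.seed(1)
  fit <- rf_fit(x, y, n_trees = 100, mtry = 2)

  # a feature the model cannot use (constant in training) gives a flat curve
  xc <- cbind(x[, "a", drop = FALSE], unused = rep(0, 300))
  set.seed(1)
  fitc <- rf_fit(xc, y, n_trees = 30, mtry = 2)
  pd_ign <- partial_dependence(fitc, xc, "unused",
                               grid = list(unused = seq(-1, 1, by = 0.5)))
  expect_equal(diff(range(pd_ign$estimate)), 0)

  # additive ground truth: 2-D surface ~ sum of 1-D curves
  pd_a <- partial_dependence(fit, x, "a", grid_size = 8)
  pd_b <- partial_dependence(fit, x, "b", grid_size = 8)
  pd_ab <- partial_dependence(fit, x, c("a", "b"),
                              grid = list(a = pd_a$a, b = pd_b$b))
  recon <- outer(pd_a$estimate, pd_b$estimate, `+`) - mean(predict(fit, x))
  surface <- matrix(pd_ab$estimate, nrow = 8)  # a varies fastest
  rng <- diff(range(surface))
  expect_lt(max(abs(surface - recon)), 0.1 * rng)

  # clamping at an observed value with n = 1 equals the model prediction
  x1 <- x[1, , drop = FALSE]
  pd1 <- partial_dependence(fit, x1, "a", grid = list(a = x1[1, "a"]))
  expect_equal(pd1$estimate, predict(fit, x1))

  expect_error(partial_dependence(fit, x, "zz"), "unknown feature")
})
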