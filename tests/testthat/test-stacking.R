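test_that("cv_scheme partitions subjects and reshuffles across repeats", {
  cv <- cv_scheme(57, n_folds = 10, n_repeats = 4, seed = 3)
  for (r in 1:4) {
    expect_setequal(unique(cv$folds[, r]), 1:10)
    expect_true(all(table(cv$folds[, r]) %in% c(5, 6)))
  }
  expect_false(identical(cv$folds[, 1], cv$folds[, 2]))
  expect_identical(cv$folds, cv_scheme(57, 10, 4, seed = 3)$folds)
})

test_that("out-of-fold predictions respect masks and never leak", {
  ds <- make_small_dataset(n = 100, seed = 21, missingness = "MCAR",
                           miss_rate = 0.25)
  cv <- cv_scheme(100, n_folds = 5, n_repeats = 2, seed = 21)
  sp <- generate_oof(ds, cv)

  # mask propagation: unobserved cells missing in every repeat
  miss <- !ds$masks$weak
  expect_true(all(is.na(sp$pred[miss, "weak", ])))
  expect_true(all(!is.na(sp$pred[!miss, "weak", ])))

  # block perfectly linear in age, no noise -> near-perfect OOF
  cfg <- simulation_config(100, block_specs = list(
    block_spec("exact", 5, shared_signal_weight = 1, noise_sd = 0,
               private_signal_weight = 0, health_weight = 0)), seed = 22)
  ds2 <- simulate_multimodal(cfg)
  sp2 <- generate_oof(ds2, cv_scheme(100, 5, 1, seed = 22))
  expect_lt(mae(sp2$pred[, 1, 1], ds2$subjects$age), 0.1)

  # pure-noise block scores at chance (within 10% of dummy over seeds)
  ratios <- sapply(1:5, function(seed) {
    cfgn <- simulation_config(150, block_specs = list(
      block_spec("noise", 10, shared_signal_weight = 0,
                 health_weight = 0)), seed = seed)
    dsn <- simulate_multimodal(cfgn)
    cvn <- cv_scheme(150, 5, 1, seed = seed)
    spn <- generate_oof(dsn, cvn)
    solo <- solo_fold_scores(spn, "noise")
    dummy <- dummy_fold_scores(dsn$subjects$age, cvn)
    mean(solo$mae) / mean(dummy$mae)
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("double coding turns missingness into sentinel features", {
  x <- matrix(c(23.5, NA, 60.1), ncol = 1,
              dimnames = list(NULL, "meg"))
  coded <- double_code(x)
  expect_equal(coded[, "meg_low"], c(23.5, -1000, 60.1))
  expect_equal(coded[, "meg_high"], c(23.5, 1000, 60.1))

  # no missing cells: the two copies are identical
  full <- matrix(rnorm(12), 4, 3)
  cf <- double_code(full)
  expect_equal(cf[, seq(1, 6, by = 2)], cf[, seq(2, 6, by = 2)],
                   ignore_attr = TRUE)
  expect_equal(unname(cf[, 1]), full[, 1])

  # all cells missing: constant sentinel pair
  allmiss <- matrix(NA_real_, 3, 1)
  ca <- double_code(allmiss)
  expect_true(all(ca[, 1] == -1000) && all(ca[, 2] == 1000))

  # ambiguity guard
  expect_error(double_code(matrix(c(1000, 2), 2, 1)), "ambiguous")
})

test_that("layer-2 splits coincide bit-exactly with layer-1 splits", {
  ds <- make_small_dataset(n = 80, seed = 31, missingness = "MCAR",
                           miss_rate = 0.2)
  cv <- cv_scheme(80, n_folds = 4, n_repeats = 2, seed = 31)
  sp <- generate_oof(ds, cv)
  m <- fit_stacker(sp, forest_spec(n_trees = 30), seed = 31)
  # the model's fold scores enumerate exactly the scheme's splits
  expect_equal(
    dplyr::arrange(as_tibble(m$fold_scores), rep, fold)[c("rep", "fold")],
    tidyr::expand_grid(rep = 1:2, fold = 1:4), ignore_attr = TRUE)
  # identical scheme object consumed by both layers
  expect_identical(m$cv$folds, sp$cv$folds)
  # every subject got one layer-2 OOF prediction per repeat
  expect_true(all(is.finite(m$oof)))
})

test_that("opportunistic equals restricted on complete cases (same seed)", {
  ds <- make_small_dataset(n = 90, seed = 41)  # fully observed
  cv <- cv_scheme(90, n_folds = 5, n_repeats = 2, seed = 41)
  m1 <- opportunistic_stack(ds, cv, forest = forest_spec(n_trees = 50),
                            seed = 41)
  m2 <- opportunistic_stack(ds, cv, forest = forest_spec(n_trees = 50),
                            seed = 41)
  expect_identical(m1$oof, m2$oof)

  # coded matrix on complete data is an exact column duplication
  coded <- double_code(m1$stacked_predictions, repeat_ = 1L)
  expect_equal(coded[, seq(1, 5, by = 2)], coded[, seq(2, 6, by = 2)],
                   ignore_attr = TRUE)

  # complete-data subjects predict identically through the full path
  pred <- predict_opportunistic(m1, ds$blocks)
  pred_masked <- predict_opportunistic(
    m1, ds$blocks, masks = lapply(ds$masks, identity))
  expect_identical(pred, pred_masked)
})

test_that("prediction with arbitrary availability degrades gracefully", {
  # the strong block is frequently missing, so the forest has seen the
  # weak-only availability pattern during training
  cfg <- simulation_config(
    150, block_specs = list(
      block_spec("strong", 15, shared_signal_weight = 1.5, noise_sd = 1,
                 missingness = "MCAR", miss_rate = 0.4),
      block_spec("weak", 15, shared_signal_weight = 0.5, noise_sd = 2),
      block_spec("noise", 15, shared_signal_weight = 0, health_weight = 0)),
    seed = 51)
  ds <- simulate_multimodal(cfg)
  cv <- cv_scheme(150, n_folds = 5, n_repeats = 2, seed = 51)
  m <- opportunistic_stack(ds, cv, forest = forest_spec(n_trees = 100),
                           seed = 51)

  # weak-only subjects track the weak-subgroup error, not the full error
  n <- 150
  masks_weak <- list(strong = rep(FALSE, n), weak = rep(TRUE, n),
                     noise = rep(FALSE, n))
  pred_weak <- predict_opportunistic(m, ds$blocks, masks = masks_weak)
  pred_full <- predict_opportunistic(
    m, ds$blocks, masks = list(strong = rep(TRUE, n), weak = rep(TRUE, n),
                               noise = rep(TRUE, n)))
  err_weak <- mae(pred_weak, ds$subjects$age)
  err_full <- mae(pred_full, ds$subjects$age)
  solo_weak <- mean(solo_fold_scores(m$stacked_predictions, "weak")$mae)
  expect_gt(err_weak, err_full)           # degraded without the strong block
  # closer to the weak-block error regime than to the full-model regime
  expect_lt(abs(err_weak - solo_weak), abs(err_weak - err_full))

  # all blocks missing -> rejection; unknown block -> error
  masks_none <- lapply(masks_weak, function(m_) rep(FALSE, n))
  expect_error(predict_opportunistic(m, ds$blocks, masks = masks_none),
               "at least one modality")
  expect_error(predict_opportunistic(m, list(other = ds$blocks$strong)),
               "unknown block")
})

test_that("sentinel magnitude does not change the stacked model", {
  ds <- make_small_dataset(n = 80, seed = 61, missingness = "MCAR",
                           miss_rate = 0.2)
  cv <- cv_scheme(80, n_folds = 4, n_repeats = 1, seed = 61)
  sp <- generate_oof(ds, cv)
  m1 <- fit_stacker(sp, forest_spec(n_trees = 50),
                    sentinels = c(-1000, 1000), seed = 61)
  m2 <- fit_stacker(sp, forest_spec(n_trees = 50),
                    sentinels = c(-1e6, 1e6), seed = 61)
  expect_identical(m1$oof, m2$oof)
})

test_that("missingness diagnostic demands missingness", {
  ds <- make_small_dataset(n = 60, seed = 71)
  cv <- cv_scheme(60, n_folds = 3, n_repeats = 1, seed = 71)
  sp <- generate_oof(ds, cv)
  expect_error(missingness_diagnostic(sp), "undefined")
})
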