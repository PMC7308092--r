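#' Mean absolute error
#'
#' @param pred,truth Aligned finite numeric vectors.
#' @return MAE in the target's units (years for age).
#' @export
mae <- function(pred, truth) {
  if (!length(pred)) abort("empty input.")
  if (length(pred) != length(truth)) abort("length mismatch.")
  mean(abs(pred - truth))
}

#' Chance-level (dummy) predictions
#'
#' Predicts the training-set target mean for every test case; the chance
#' baseline every model must beat.
#'
#' @param y_train Training targets (non-empty).
#' @param y_test Test targets (only their number is used).
#' @return Constant prediction vector of length `length(y_test)`.
#' @export
dummy_baseline <- function(y_train, y_test) {
  if (!length(y_train)) abort("empty training target.")
  rep(mean(y_train), length(y_test))
}

new_fold_scores <- function(df, cv) {
  out <- as_tibble(df)
  attr(out, "cv_key") <- cv_key(cv)
  class(out) <- c("fold_scores", class(out))
  out
}

#' Fold-wise chance-level scores under a CV scheme
#'
#' Uses the identical splits as the non-trivial models (the scheme object
#' is shared), which is what makes the fold-wise comparison paired.
#'
#' @param y Target vector.
#' @param cv A [cv_scheme()].
#' @return A `fold_scores` tibble with one MAE per (repeat, fold).
#' @export
dummy_fold_scores <- function(y, cv) {
  rows <- list()
  for (r in seq_len(cv$n_repeats)) {
    fold_of <- cv$folds[, r]
    for (f in seq_len(cv$n_folds)) {
      te <- fold_of == f
      rows[[length(rows) + 1L]] <-
        tibble(model = "chance", rep = r, fold = f,
               mae = mae(dummy_baseline(y[!te], y[te]), y[te]))
    }
  }
  new_fold_scores(dplyr::bind_rows(rows), cv)
}

check_aligned <- function(a, ref) {
  ka <- attr(a, "cv_key")
  kr <- attr(ref, "cv_key")
  if (!identical(ka, kr)) abort("fold scores come from different CV schemes.")
  a_ord <- dplyr::arrange(a, .data$rep, .data$fold)
  r_ord <- dplyr::arrange(ref, .data$rep, .data$fold)
  if (!identical(a_ord[c("rep", "fold")], r_ord[c("rep", "fold")])) {
    abort("misaligned folds.")
  }
  list(a = a_ord, ref = r_ord)
}

#' Paired fold-wise model comparison
#'
#' Summarizes the distribution of split-wise MAE differences
#' `candidate - reference` over the shared (fold x repeat) splits: mean,
#' SD, the 2.5/97.5 percentiles, and the fraction of splits in which the
#' candidate was strictly better (`pr_better`, i.e. Pr<Ref).
#'
#' @param a Candidate `fold_scores`.
#' @param ref Reference `fold_scores` from the same CV scheme.
#' @return One-row tibble of class `paired_comparison`.
#' @export
paired_compare <- function(a, ref) {
  al <- check_aligned(a, ref)
  d <- al$a$mae - al$ref$mae
  out <- tibble(
    candidate = al$a$model[1L], reference = al$ref$model[1L],
    mean_diff = mean(d), sd_diff = sd(d),
    p2.5 = unname(quantile(d, 0.025)), p97.5 = unname(quantile(d, 0.975)),
    pr_better = mean(al$a$mae < al$ref$mae), n_splits = length(d))
  class(out) <- c("paired_comparison", class(out))
  out
}

#' Rank stability across models
#'
#' Per (repeat, fold) split, models are ranked by MAE (1 = best, ties get
#' the average rank); returns the frequency of each rank per model and
#' pairwise strict-win fractions.
#'
#' @param scores Named list of `fold_scores` (>= 2 models) sharing a CV
#'   scheme.
#' @return List of class `model_ranking` with `ranks`, `rank_freq`,
#'   `pairwise`.
#' @export
rank_models <- function(scores) {
  if (length(scores) < 2L) abort("at least two models are required.")
  base <- scores[[1L]]
  aligned <- lapply(scores, function(s) check_aligned(s, base)$a)
  mat <- vapply(aligned, function(s) s$mae, numeric(nrow(base)))
  colnames(mat) <- names(scores) %||%
    vapply(aligned, function(s) s$model[1L], "")
  ranks <- t(apply(mat, 1L, rank))
  rank_freq <- dplyr::count(
    tibble(model = rep(colnames(mat), each = nrow(mat)),
           rank = as.vector(ranks)),
    .data$model, .data$rank, name = "freq")
  k <- ncol(mat)
  pairwise <- matrix(NA_real_, k, k, dimnames = list(colnames(mat),
                                                     colnames(mat)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) pairwise[i, j] <- mean(mat[, i] < mat[, j])
    }
  }
  structure(list(ranks = ranks, rank_freq = rank_freq, pairwise = pairwise,
                 n_splits = nrow(mat)),
            class = "model_ranking")
}

#' Reproducible permutation stream
#'
#' Deterministic permutation used by [permutation_importance()], seeded per
#' (feature, permutation index) so importances are exactly reproducible and
#' independently recomputable.
#'
#' @param seed Base seed.
#' @param feature Feature index.
#' @param perm Permutation index in `1..k`.
#' @param n Number of rows.
#' @return Integer permutation of `1..n`.
#' @export
permutation_stream <- function(seed, feature, perm, n) {
  with_seed(derive_seed(seed, 100003L * feature + perm), sample.int(n))
}

#' Permutation variable importance
#'
#' Importance of a feature is the mean increase in MAE over `k` shuffles of
#' its column, in outcome units (years). `scope = "in_sample"` permutes the
#' supplied data under the fitted model; `scope = "out_of_sample"` refits
#' the model per CV split and permutes the test-split columns (`k` is then
#' typically reduced, e.g. 100 instead of 1000).
#'
#' @param model A fitted model with a `predict` method (for in-sample).
#' @param x,y Data aligned with the model's features.
#' @param k Number of permutations per feature (>= 1).
#' @param scope `"in_sample"` or `"out_of_sample"`.
#' @param cv A [cv_scheme()], required for out-of-sample scope.
#' @param refit Function `(x, y) -> model`, required for out-of-sample
#'   scope.
#' @param seed Base seed of the permutation streams.
#' @return Tibble with `feature`, `importance` (years of MAE increase) and
#'   `sd` across permutations (and splits, for out-of-sample).
#' @export
permutation_importance <- function(model, x, y, k = 1000L,
                                   scope = c("in_sample", "out_of_sample"),
                                   cv = NULL, refit = NULL, seed = 0L) {
  scope <- match.arg(scope)
  if (k < 1L) abort("`k` must be >= 1.")
  x <- as.matrix(x)
  nm <- colnames(x) %||% sprintf("x%d", seq_len(ncol(x)))
  if (scope == "in_sample") {
    base <- mae(predict(model, x), y)
    rows <- lapply(seq_len(ncol(x)), function(j) {
      deltas <- vapply(seq_len(k), function(i) {
        xp <- x
        xp[, j] <- xp[permutation_stream(seed, j, i, nrow(x)), j]
        mae(predict(model, xp), y) - base
      }, numeric(1))
      tibble(feature = nm[j], importance = mean(deltas),
             sd = if (k > 1L) sd(deltas) else NA_real_)
    })
    return(dplyr::bind_rows(rows))
  }
  if (is.null(cv) || is.null(refit)) {
    abort("out-of-sample scope needs `cv` and `refit`.")
  }
  per_split <- list()
  for (r in seq_len(cv$n_repeats)) {
    fold_of <- cv$folds[, r]
    for (f in seq_len(cv$n_folds)) {
      tr <- fold_of != f
      fit <- refit(x[tr, , drop = FALSE], y[tr])
      xt <- x[!tr, , drop = FALSE]
      yt <- y[!tr]
      base <- mae(predict(fit, xt), yt)
      for (j in seq_len(ncol(x))) {
        deltas <- vapply(seq_len(k), function(i) {
          xp <- xt
          xp[, j] <- xp[permutation_stream(seed + r * 1000L + f, j, i,
                                           nrow(xt)), j]
          mae(predict(fit, xp), yt) - base
        }, numeric(1))
        per_split[[length(per_split) + 1L]] <-
          tibble(feature = nm[j], rep = r, fold = f,
                 importance = mean(deltas))
      }
    }
  }
  dplyr::summarise(dplyr::group_by(dplyr::bind_rows(per_split),
                                   .data$feature),
                   sd = sd(.data$importance),
                   importance = mean(.data$importance),
                   .groups = "drop")[, c("feature", "importance", "sd")]
}

#' Mean-decrease-impurity importance
#'
#' Sums, across all trees of a forest, the MSE-impurity reduction
#' attributable to each feature; returned normalized to sum to 1.
#'
#' @param model An [rf_fit()] forest.
#' @return Tibble with `feature` and `importance` (impurity share).
#' @export
mdi_importance <- function(model) {
  if (!inherits(model, "rf_model")) abort("`model` must be a fitted forest.")
  imp <- model$mdi
  total <- sum(imp)
  tibble(feature = model$feature_names,
         importance = if (total > 0) imp / total else imp)
}

#' Partial dependence
#'
#' Mean model prediction over the data with one or two selected features
#' clamped to each grid point.
#'
#' @param model Fitted model with a `predict` method.
#' @param x Data matrix the model was trained on.
#' @param features One or two feature names (or indices).
#' @param grid_size Grid points per feature (evenly spaced over the
#'   observed range); alternatively pass explicit values via `grid`.
#' @param grid Optional named list of explicit grid values per feature.
#' @return Tibble of class `partial_dependence`: grid columns plus
#'   `estimate`.
#' @export
partial_dependence <- function(model, x, features, grid_size = 20L,
                               grid = NULL) {
  x <- as.matrix(x)
  nm <- colnames(x) %||% sprintf("x%d", seq_len(ncol(x)))
  idx <- if (is.character(features)) match(features, nm) else
    as.integer(features)
  if (anyNA(idx)) abort("unknown feature.")
  if (!length(idx) %in% 1:2) abort("1 or 2 features are supported.")
  grids <- lapply(seq_along(idx), function(i) {
    g <- grid[[nm[idx[i]]]]
    g %||% seq(min(x[, idx[i]]), max(x[, idx[i]]), length.out = grid_size)
  })
  combos <- expand.grid(grids)
  names(combos) <- nm[idx]
  est <- vapply(seq_len(nrow(combos)), function(r) {
    xg <- x
    for (i in seq_along(idx)) xg[, idx[i]] <- combos[r, i]
    mean(predict(model, xg))
  }, numeric(1))
  out <- as_tibble(combos)
  out$estimate <- est
  class(out) <- c("partial_dependence", class(out))
  out
}
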