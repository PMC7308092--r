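#' Shared cross-validation scheme
#'
#' A 10-fold scheme repeated 10 times with reshuffling, stored as an
#' explicit subject x repeat fold-assignment matrix. The same object is
#' consumed bit-exactly by layer 1 (per-block ridge), layer 2 (forest
#' combiner) and the chance baseline, which is what makes fold-wise paired
#' model comparisons valid.
#'
#' @param n_subjects Number of subjects.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats with reshuffling (default 10).
#' @param seed Integer seed for the per-repeat permutations.
#' @return A `cv_scheme` with `folds` (n_subjects x n_repeats integer
#'   matrix of fold labels).
#' @export
cv_scheme <- function(n_subjects, n_folds = 10L, n_repeats = 10L, seed = 1L) {
  if (n_folds < 2L || n_folds > n_subjects) {
    abort("`n_folds` must be in [2, n_subjects].")
  }
  folds <- with_seed(derive_seed(seed, 31L), {
    vapply(seq_len(n_repeats), function(r) {
      labels <- rep(seq_len(n_folds), length.out = n_subjects)
      labels[order(sample.int(n_subjects))]
    }, integer(n_subjects))
  })
  structure(list(n_subjects = as.integer(n_subjects),
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), folds = folds),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %d subjects, %d folds x %d repeats (seed %d)\n",
              x$n_subjects, x$n_folds, x$n_repeats, x$seed))
  invisible(x)
}

cv_key <- function(cv) {
  list(n_subjects = cv$n_subjects, n_folds = cv$n_folds,
       n_repeats = cv$n_repeats, seed = cv$seed)
}

#' Out-of-fold layer-1 age predictions per block
#'
#' For every repeat, fold and block, a ridge model (penalty tuned by GCV)
#' is fit on the observed training-fold rows of that block and used to
#' predict the observed test-fold rows, so every observed (subject, block)
#' cell receives exactly one prediction per repeat, always from a model
#' that never saw that subject in that repeat. Unobserved cells stay
#' flagged missing.
#'
#' @param dataset A `multimodal_dataset` (see [simulate_multimodal()], or
#'   build one from files with [read_multimodal()]).
#' @param cv A [cv_scheme()] covering all subjects.
#' @param spec A [ridge_spec()].
#' @return A `stacked_predictions`: `pred` (subjects x blocks x repeats
#'   array, NA where unobserved), `mask` (subjects x blocks), `age`, `cv`,
#'   and the per-(block, repeat, fold) selected penalties.
#' @export
generate_oof <- function(dataset, cv, spec = ridge_spec()) {
  stopifnot(inherits(dataset, "multimodal_dataset"),
            inherits(cv, "cv_scheme"))
  n <- nrow(dataset$subjects)
  if (cv$n_subjects != n) abort("CV scheme does not cover the dataset.")
  blocks <- names(dataset$blocks)
  m <- length(blocks)
  y <- dataset$subjects$age
  pred <- array(NA_real_, dim = c(n, m, cv$n_repeats),
                dimnames = list(dataset$subjects$subject_id, blocks, NULL))
  mask <- do.call(cbind, dataset$masks)
  colnames(mask) <- blocks
  lambdas <- list()
  for (r in seq_len(cv$n_repeats)) {
    fold_of <- cv$folds[, r]
    for (j in seq_len(m)) {
      xj <- dataset$blocks[[j]]
      obs <- mask[, j]
      for (f in seq_len(cv$n_folds)) {
        tr <- obs & fold_of != f
        te <- obs & fold_of == f
        if (sum(tr) < 2L) {
          abort(sprintf(
            "block '%s', repeat %d, fold %d: fewer than 2 observed training rows.",
            blocks[j], r, f))
        }
        fit <- fit_ridge_gcv(xj[tr, , drop = FALSE], y[tr], spec)
        if (any(te)) {
          pred[te, j, r] <- predict(fit, xj[te, , drop = FALSE])
        }
        lambdas[[length(lambdas) + 1L]] <-
          tibble(block = blocks[j], rep = r, fold = f, lambda = fit$lambda)
      }
    }
  }
  structure(list(pred = pred, mask = mask, age = y, cv = cv,
                 blocks = blocks,
                 lambdas = dplyr::bind_rows(lambdas)),
            class = "stacked_predictions")
}

#' @export
print.stacked_predictions <- function(x, ...) {
  cat(sprintf(
    "<stacked_predictions> %d subjects x %d blocks x %d repeats (%.1f%% cells missing)\n",
    dim(x$pred)[1], dim(x$pred)[2], dim(x$pred)[3],
    100 * mean(!x$mask)))
  invisible(x)
}

#' Double-code a prediction matrix for opportunistic learning
#'
#' Every column is duplicated; missing cells receive a low sentinel in the
#' first copy and a high sentinel in the second, while observed cells are
#' copied to both. This turns missingness into features: the forest can
#' split subjects with a missing block off to either side, at either
#' sentinel, and learn from them. Sentinels default to the biologically
#' implausible ages -1000 and +1000.
#'
#' @param x Subjects x blocks prediction matrix (one repeat), or a
#'   `stacked_predictions` (then `repeat_` selects the repeat).
#' @param mask Logical observed-cell matrix matching `x` (defaults to
#'   `!is.na(x)`).
#' @param sentinels `(low, high)` fill values, outside the plausible
#'   prediction range.
#' @param repeat_ Repeat index when `x` is a `stacked_predictions`.
#' @return Subjects x 2m matrix with columns `<block>_low`, `<block>_high`.
#' @export
double_code <- function(x, mask = NULL, sentinels = c(-1000, 1000),
                        repeat_ = 1L) {
  if (inherits(x, "stacked_predictions")) {
    mask <- mask %||% x$mask
    x <- x$pred[, , repeat_, drop = FALSE]
    dim(x) <- dim(mask)
    dimnames(x) <- dimnames(mask)
  }
  x <- as.matrix(x)
  mask <- mask %||% !is.na(x)
  if (sentinels[1] >= sentinels[2]) abort("sentinels must be (low, high).")
  if (any(x[mask] %in% sentinels)) {
    abort("an observed value equals a sentinel; coding would be ambiguous.")
  }
  m <- ncol(x)
  nm <- colnames(x) %||% sprintf("b%d", seq_len(m))
  out <- matrix(NA_real_, nrow = nrow(x), ncol = 2L * m)
  colnames(out) <- as.vector(rbind(paste0(nm, "_low"), paste0(nm, "_high")))
  for (j in seq_len(m)) {
    lo <- x[, j]
    hi <- x[, j]
    lo[!mask[, j]] <- sentinels[1]
    hi[!mask[, j]] <- sentinels[2]
    out[, 2L * j - 1L] <- lo
    out[, 2L * j] <- hi
  }
  out
}

#' Fit the layer-2 forest combiner on double-coded stacked predictions
#'
#' Per repeat, the stacked out-of-fold matrix is double-coded and a forest
#' is fit per fold on the training rows of the shared [cv_scheme()] (so
#' layer-2 train/test splits coincide bit-exactly with layer-1's), giving
#' layer-2 out-of-fold predictions and fold-wise MAEs. Depth and mtry are
#' tuned by inner 5-fold grid search scored by MAE; with
#' `tune = "per_repeat"` (default) the grid search runs once per repeat on
#' the training rows of the first fold split, with `tune = "per_fold"` it
#' is fully nested (about 10x the cost). One final forest per repeat is
#' also fit on all rows for deployment and importance analysis.
#'
#' @param sp A [generate_oof()] result.
#' @param spec A [forest_spec()].
#' @param sentinels Passed to [double_code()].
#' @param tune Tuning granularity, `"per_repeat"` or `"per_fold"`.
#' @param seed Integer seed for tuning folds, tree bootstrap and feature
#'   sampling.
#' @return A `stacked_model` with per-repeat forests and tuned parameters,
#'   the layer-2 out-of-fold prediction matrix (subjects x repeats), and
#'   fold-wise MAE scores.
#' @export
fit_stacker <- function(sp, spec = forest_spec(), sentinels = c(-1000, 1000),
                        tune = c("per_repeat", "per_fold"), seed = 1L) {
  stopifnot(inherits(sp, "stacked_predictions"))
  tune <- match.arg(tune)
  cv <- sp$cv
  y <- sp$age
  n <- length(y)
  oof <- matrix(NA_real_, nrow = n, ncol = cv$n_repeats)
  forests <- vector("list", cv$n_repeats)
  tuned <- vector("list", cv$n_repeats)
  scores <- list()
  for (r in seq_len(cv$n_repeats)) {
    coded <- double_code(sp, sentinels = sentinels, repeat_ = r)
    fold_of <- cv$folds[, r]
    with_seed(derive_seed(seed, 7000L + r), {
      params <- NULL
      if (tune == "per_repeat") {
        tr1 <- fold_of != 1L
        params <- rf_tune(coded[tr1, , drop = FALSE], y[tr1], spec)
      }
      for (f in seq_len(cv$n_folds)) {
        tr <- fold_of != f
        if (tune == "per_fold") {
          params <- rf_tune(coded[tr, , drop = FALSE], y[tr], spec)
        }
        fit <- rf_fit(coded[tr, , drop = FALSE], y[tr],
                      n_trees = spec$n_trees, mtry = params$mtry,
                      max_depth = params$max_depth)
        oof[!tr, r] <- predict(fit, coded[!tr, , drop = FALSE])
        scores[[length(scores) + 1L]] <-
          tibble(model = "stacked", rep = r, fold = f,
                 mae = mae(oof[!tr, r], y[!tr]))
      }
      forests[[r]] <- rf_fit(coded, y, n_trees = spec$n_trees,
                             mtry = params$mtry,
                             max_depth = params$max_depth)
      tuned[[r]] <- tibble(rep = r, max_depth = params$max_depth,
                           mtry = params$mtry)
    })
  }
  structure(list(
    forests = forests, tuned = dplyr::bind_rows(tuned),
    oof = oof, fold_scores = new_fold_scores(dplyr::bind_rows(scores), cv),
    cv = cv, sentinels = sentinels, blocks = sp$blocks, spec = spec,
    age = y, subject_ids = rownames(sp$mask)),
    class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d blocks, %d repeats; mean OOF MAE %.2f years\n",
              length(x$blocks), x$cv$n_repeats,
              mean(x$fold_scores$mae)))
  invisible(x)
}

#' @export
tidy.stacked_model <- function(x, ...) {
  as_tibble(x$fold_scores)
}

#' @export
glance.stacked_model <- function(x, ...) {
  tibble(mae = mean(x$fold_scores$mae), mae_sd = sd(x$fold_scores$mae),
         n_blocks = length(x$blocks), n_folds = x$cv$n_folds,
         n_repeats = x$cv$n_repeats, n = length(x$age))
}

#' Per-subject consensus age prediction
#'
#' The reporting convention: each subject's out-of-fold layer-2 prediction
#' averaged across CV repeats.
#'
#' @param model A [fit_stacker()] result.
#' @return Tibble with `subject_id`, `age`, `predicted`, `delta`.
#' @export
consensus_predictions <- function(model) {
  stopifnot(inherits(model, "stacked_model"))
  pred <- rowMeans(model$oof)
  tibble(subject_id = model$subject_ids %||%
           sprintf("S%04d", seq_along(pred)),
         age = model$age, predicted = pred, delta = pred - model$age)
}

#' Fit the full opportunistic stacking pipeline
#'
#' Convenience wrapper: layer-1 out-of-fold predictions, layer-2 forest,
#' plus one deployment ridge model per block fit on all its observed rows
#' (used by [predict_opportunistic()] for new subjects).
#'
#' @param dataset A `multimodal_dataset`.
#' @param cv A [cv_scheme()]; defaults to 10 x 10.
#' @param ridge A [ridge_spec()].
#' @param forest A [forest_spec()].
#' @inheritParams fit_stacker
#' @return A `stacked_model` with an extra `layer1` element.
#' @export
opportunistic_stack <- function(dataset, cv = NULL, ridge = ridge_spec(),
                                forest = forest_spec(),
                                sentinels = c(-1000, 1000),
                                tune = "per_repeat", seed = 1L) {
  cv <- cv %||% cv_scheme(nrow(dataset$subjects), seed = seed)
  sp <- generate_oof(dataset, cv, ridge)
  model <- fit_stacker(sp, forest, sentinels = sentinels, tune = tune,
                       seed = seed)
  model$layer1 <- lapply(setNames(names(dataset$blocks),
                                  names(dataset$blocks)), function(b) {
    obs <- dataset$masks[[b]]
    fit_ridge_gcv(dataset$blocks[[b]][obs, , drop = FALSE],
                  dataset$subjects$age[obs], ridge)
  })
  model$stacked_predictions <- sp
  model
}

#' Predict new subjects with arbitrary modality availability
#'
#' Layer-1 predictions are computed for each observed block, double-coded
#' with the training sentinels, and passed through the per-repeat forests
#' (averaged). Subjects with no observed block are rejected: the model
#' needs at least one modality.
#'
#' @param model An [opportunistic_stack()] result.
#' @param blocks Named list of new feature matrices (names must match the
#'   training blocks).
#' @param masks Named list of logical availability vectors; defaults to
#'   all-observed.
#' @return Numeric vector of predicted ages (years).
#' @export
predict_opportunistic <- function(model, blocks, masks = NULL) {
  stopifnot(inherits(model, "stacked_model"))
  if (is.null(model$layer1)) {
    abort("model has no deployment layer-1 fits; use opportunistic_stack().")
  }
  unknown <- setdiff(names(blocks), model$blocks)
  if (length(unknown)) {
    abort(sprintf("unknown block name(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  n <- nrow(blocks[[1L]])
  m <- length(model$blocks)
  pred <- matrix(NA_real_, nrow = n, ncol = m,
                 dimnames = list(NULL, model$blocks))
  mask <- matrix(FALSE, nrow = n, ncol = m,
                 dimnames = list(NULL, model$blocks))
  for (b in names(blocks)) {
    obs <- masks[[b]] %||% rep(TRUE, n)
    mask[, b] <- obs
    if (any(obs)) {
      pred[obs, b] <- predict(model$layer1[[b]],
                              blocks[[b]][obs, , drop = FALSE])
    }
  }
  if (any(rowSums(mask) == 0L)) {
    abort("subject(s) with no observed block: at least one modality is required.")
  }
  coded <- double_code(pred, mask, sentinels = model$sentinels)
  rowMeans(vapply(model$forests, function(fit) predict(fit, coded),
                  numeric(n)))
}

#' Missingness-informativeness diagnostic
#'
#' Refits the opportunistic forest with the observed cells set to zero so
#' that only the missing-value coding remains informative, scores it with
#' the shared CV scheme, and compares it fold-wise against the chance
#' (training-mean) baseline. Under MCAR missingness the diagnostic performs
#' at chance; age-dependent missingness makes it beat chance, revealing
#' that the model can read age off the missingness pattern.
#'
#' @param sp A [generate_oof()] result with some missingness.
#' @param spec A [forest_spec()].
#' @param sentinels Passed to [double_code()].
#' @param seed Integer seed.
#' @return List with the `comparison` ([paired_compare()] row against the
#'   dummy baseline) and both fold-score tables.
#' @export
missingness_diagnostic <- function(sp, spec = forest_spec(),
                                   sentinels = c(-1000, 1000), seed = 1L) {
  stopifnot(inherits(sp, "stacked_predictions"))
  if (all(sp$mask)) {
    abort("no missingness present: the diagnostic is undefined.")
  }
  cv <- sp$cv
  y <- sp$age
  zeroed <- matrix(0, nrow = nrow(sp$mask), ncol = ncol(sp$mask),
                   dimnames = dimnames(sp$mask))
  coded <- double_code(zeroed, sp$mask, sentinels = sentinels)
  scores <- list()
  for (r in seq_len(cv$n_repeats)) {
    fold_of <- cv$folds[, r]
    with_seed(derive_seed(seed, 9000L + r), {
      tr1 <- fold_of != 1L
      params <- rf_tune(coded[tr1, , drop = FALSE], y[tr1], spec)
      for (f in seq_len(cv$n_folds)) {
        tr <- fold_of != f
        fit <- rf_fit(coded[tr, , drop = FALSE], y[tr],
                      n_trees = spec$n_trees, mtry = params$mtry,
                      max_depth = params$max_depth)
        scores[[length(scores) + 1L]] <-
          tibble(model = "missingness", rep = r, fold = f,
                 mae = mae(predict(fit, coded[!tr, , drop = FALSE]), y[!tr]))
      }
    })
  }
  diag_scores <- new_fold_scores(dplyr::bind_rows(scores), cv)
  dummy <- dummy_fold_scores(y, cv)
  list(comparison = paired_compare(diag_scores, dummy),
       scores = diag_scores, dummy = dummy)
}

#' Fold-wise scores for a single block's layer-1 model
#'
#' Extracts the out-of-fold MAE of one block's ridge predictions (observed
#' rows only), aligned to the shared CV scheme, for solo-vs-stacked
#' comparisons.
#'
#' @param sp A [generate_oof()] result.
#' @param block Block name.
#' @return A fold-scores tibble (class `fold_scores`).
#' @export
solo_fold_scores <- function(sp, block) {
  stopifnot(inherits(sp, "stacked_predictions"))
  j <- match(block, sp$blocks)
  if (is.na(j)) abort(sprintf("unknown block '%s'.", block))
  cv <- sp$cv
  rows <- list()
  for (r in seq_len(cv$n_repeats)) {
    fold_of <- cv$folds[, r]
    for (f in seq_len(cv$n_folds)) {
      te <- sp$mask[, j] & fold_of == f
      rows[[length(rows) + 1L]] <-
        tibble(model = block, rep = r, fold = f,
               mae = if (any(te)) mae(sp$pred[te, j, r], sp$age[te])
                     else NA_real_)
    }
  }
  new_fold_scores(dplyr::bind_rows(rows), cv)
}
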