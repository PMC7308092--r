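#' Regression random forest
#'
#' Bagged regression trees with mean-squared-error impurity splits, the
#' combiner used on top of the per-block linear age predictions. No random
#' forest implementation ships with this R installation, so the trees are
#' grown by compiled code in this package; splits, `mtry` sub-sampling and
#' depth limits follow the classical algorithm. Uses R's RNG, so results
#' are reproducible under [set.seed()].
#'
#' @param x Samples x features matrix (no missing values; sentinels are
#'   plain numbers here).
#' @param y Numeric target.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features considered per split; default `floor(sqrt(p))`.
#' @param max_depth Maximal tree depth; `Inf` (default) leaves trees
#'   unconstrained.
#' @param min_split Minimal node size eligible for splitting.
#' @param bootstrap Draw bootstrap replicas per tree?
#' @return An `rf_model` with `trees`, raw `mdi` impurity sums, and the
#'   settings used.
#' @export
rf_fit <- function(x, y, n_trees = 1000L, mtry = NULL, max_depth = Inf,
                   min_split = 2L, bootstrap = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) abort("missing values in `x` or `y`.")
  if (nrow(x) != length(y)) abort("`x` rows and `y` length differ.")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  depth <- if (is.infinite(max_depth)) 0L else as.integer(max_depth)
  fit <- .rf_fit_cpp(x, as.numeric(y), as.integer(n_trees),
                     as.integer(mtry), depth, as.integer(min_split),
                     isTRUE(bootstrap))
  structure(list(trees = fit$trees, mdi = as.numeric(fit$mdi),
                 feature_names = colnames(x) %||%
                   sprintf("x%d", seq_len(ncol(x))),
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 max_depth = max_depth, p = ncol(x), n = nrow(x)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) abort("feature count mismatch.")
  as.numeric(.rf_predict_cpp(object$trees, newdata))
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry = %d, max_depth = %s, p = %d\n",
              x$n_trees, x$mtry, format(x$max_depth), x$p))
  invisible(x)
}

#' @export
tidy.rf_model <- function(x, ...) {
  mdi_importance(x)
}

#' Random-forest combiner specification
#'
#' Tuning grids for the layer-2 forest: 1000 trees; depth chosen among 4, 6,
#' 8 or unconstrained; features-per-split among `sqrt(p)`, `log2(p)` and all
#' `p`; selected by inner 5-fold cross-validation scored by mean absolute
#' error. Ties prefer the simpler model (smallest depth, then smallest
#' mtry).
#'
#' @param n_trees Number of trees.
#' @param depth_grid Candidate depths (use `Inf` for unconstrained).
#' @param max_features Candidate feature-sampling rules among `"sqrt"`,
#'   `"log2"`, `"all"`.
#' @param inner_folds Folds of the tuning cross-validation.
#' @return A `forest_spec` list.
#' @export
forest_spec <- function(n_trees = 1000L, depth_grid = c(4, 6, 8, Inf),
                        max_features = c("sqrt", "log2", "all"),
                        inner_folds = 5L) {
  if (!length(depth_grid) || !length(max_features)) {
    abort("tuning grids must be non-empty.")
  }
  structure(list(n_trees = as.integer(n_trees), depth_grid = depth_grid,
                 max_features = match.arg(max_features, several.ok = TRUE),
                 inner_folds = as.integer(inner_folds)),
            class = "forest_spec")
}

mtry_value <- function(rule, p) {
  as.integer(switch(rule,
                    sqrt = max(1, floor(sqrt(p))),
                    log2 = max(1, floor(log2(p))),
                    all = p))
}

#' Tune the forest by inner cross-validated grid search
#'
#' @param x,y Training data.
#' @param spec A [forest_spec()].
#' @return List with the selected `max_depth`, `mtry`, and the full
#'   `results` tibble of grid-point MAEs.
#' @export
rf_tune <- function(x, y, spec = forest_spec()) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  folds <- rep(seq_len(spec$inner_folds), length.out = n)[sample.int(n)]
  mtries <- sort(unique(vapply(spec$max_features, mtry_value, 0L, p = p)))
  grid <- expand.grid(max_depth = sort(spec$depth_grid), mtry = mtries)
  grid$mae <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(spec$inner_folds), function(f) {
      tr <- folds != f
      fit <- rf_fit(x[tr, , drop = FALSE], y[tr], n_trees = spec$n_trees,
                    mtry = grid$mtry[g], max_depth = grid$max_depth[g])
      mae(predict(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # ties: smallest depth, then smallest mtry (grid is ordered that way)
  ord <- order(grid$mae, grid$max_depth, grid$mtry)
  best <- grid[ord[1L], ]
  list(max_depth = best$max_depth, mtry = best$mtry,
       results = as_tibble(grid))
}
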