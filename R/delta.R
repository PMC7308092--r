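#' Brain-age delta
#'
#' `delta = predicted - actual`: positive values quantify overestimation
#' (an "older-looking" brain), the sign convention under which positive
#' deltas index reduced fitness or health in the literature.
#'
#' @param pred Predicted ages (years).
#' @param age Chronological ages (years).
#' @return Numeric delta vector.
#' @export
compute_delta <- function(pred, age) {
  if (length(pred) != length(age)) abort("misaligned vectors.")
  pred - age
}

standardize <- function(x) {
  s <- sd(x)
  if (s == 0) abort("cannot standardize a constant column.")
  (x - mean(x)) / s
}

#' Residualize a score against a cubic age trend
#'
#' Both score and age are standardized, then the score is regressed on
#' `age + age^2 + age^3` (with intercept) and the residual returned. This
#' is the two-step deconfounding device that removes shared age-related
#' variance before correlating scores with the brain-age delta.
#'
#' @param score Numeric score vector.
#' @param age Ages (years), same length, at least 5 subjects.
#' @return Residual vector (standardized-score units).
#' @export
residualize_score <- function(score, age) {
  if (length(score) < 5L) abort("at least 5 subjects are required.")
  z <- standardize(age)
  s <- standardize(score)
  basis <- cbind(1, z, z^2, z^3)
  fit <- lm.fit(basis, s)
  if (fit$rank < ncol(basis)) abort("rank-deficient age polynomial basis.")
  fit$residuals
}

#' Association between a score and the brain-age delta
#'
#' Three deconfounding specifications:
#' \describe{
#'   \item{two_step}{residualize the score against the cubic age trend,
#'     then regress the (standardized) residual on the standardized delta;
#'     the standardized coefficient equals the Pearson correlation of
#'     residual and delta.}
#'   \item{joint}{`score ~ delta + age + age^2 + age^3` in one model.}
#'   \item{extended}{the joint model plus gender, binarized handedness and
#'     log Frobenius-norm head-motion variability as confounds.}
#' }
#' All continuous inputs are standardized; `beta` is the delta coefficient
#' with its two-sided p-value. No multiple-testing correction is applied;
#' annotate against the 5\%/1\%/0.1\% reference levels downstream.
#'
#' @param score Numeric score vector.
#' @param delta Brain-age delta (see [compute_delta()]; by the reporting
#'   convention, mean over CV repeats of out-of-fold predictions minus
#'   age).
#' @param age Ages in years.
#' @param confounds Data frame with columns `gender`, `handedness`,
#'   `motion_log` (required for `spec = "extended"`).
#' @param spec `"two_step"`, `"joint"` or `"extended"`.
#' @param name Score name carried into the output row.
#' @return One-row tibble: `score`, `spec`, `beta`, `p_value`, `n`.
#' @export
delta_association <- function(score, delta, age, confounds = NULL,
                              spec = c("two_step", "joint", "extended"),
                              name = "score") {
  spec <- match.arg(spec)
  n <- length(score)
  dz <- standardize(delta)
  if (spec == "two_step") {
    resid <- standardize(residualize_score(score, age))
    design <- cbind(delta = dz)
    target <- resid
  } else {
    z <- standardize(age)
    design <- cbind(delta = dz, age = z, age2 = z^2, age3 = z^3)
    if (spec == "extended") {
      req <- c("gender", "handedness", "motion_log")
      if (is.null(confounds) || !all(req %in% names(confounds))) {
        abort("extended spec requires gender, handedness and motion_log confounds.")
      }
      design <- cbind(design,
                      gender = as.numeric(confounds$gender),
                      handedness = as.numeric(confounds$handedness),
                      motion_log = standardize(confounds$motion_log))
    }
    target <- standardize(score)
  }
  dm <- cbind(`(Intercept)` = 1, design)
  qrd <- qr(dm)
  if (qrd$rank < ncol(dm)) {
    bad <- colnames(dm)[qrd$pivot[-seq_len(qrd$rank)]]
    abort(sprintf("collinear design columns: %s.",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(dm, target)
  rss <- sum(fit$residuals^2)
  dof <- n - ncol(dm)
  xtxi <- solve(crossprod(dm))
  se <- sqrt(rss / dof * diag(xtxi))
  beta <- fit$coefficients["delta"]
  tval <- beta / se[match("delta", colnames(dm))]
  tibble(score = name, spec = spec, beta = unname(beta),
         p_value = 2 * pt(abs(tval), dof, lower.tail = FALSE), n = n)
}

#' Association table across scores and specifications
#'
#' @param scores Tibble with `subject_id` and one column per score (e.g.
#'   from [simulate_scores()]).
#' @param delta,age,confounds As in [delta_association()].
#' @param specs Deconfounding specifications to run.
#' @return Tidy tibble of class `delta_association_table`, one row per
#'   (score, specification).
#' @export
delta_association_table <- function(scores, delta, age, confounds = NULL,
                                    specs = c("two_step", "joint")) {
  score_cols <- setdiff(names(scores), "subject_id")
  rows <- list()
  for (sc in score_cols) {
    for (sp in specs) {
      rows[[length(rows) + 1L]] <-
        delta_association(scores[[sc]], delta, age, confounds, sp, name = sc)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delta_association_table", class(out))
  out
}

#' Build a behavioral score catalog
#'
#' Validates a catalog of scores, each with a type (neuropsychology,
#' physiology, questionnaire), an aggregation rule (total, mean, ratio,
#' difference, PC1) and the number of variables it contributes.
#'
#' @param catalog Data frame with columns `name`, `type`, `aggregation`,
#'   `n_variables`.
#' @return Tibble of class `score_catalog`; `attr(, "total_variables")`
#'   holds the variable total.
#' @export
build_score_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  req <- c("name", "type", "aggregation", "n_variables")
  if (!all(req %in% names(catalog))) {
    abort("catalog needs name, type, aggregation, n_variables columns.")
  }
  ok_agg <- c("total", "mean", "ratio", "difference", "PC1")
  bad <- setdiff(unique(catalog$aggregation), ok_agg)
  if (length(bad)) {
    abort(sprintf("unknown aggregation tag(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  ok_type <- c("neuropsychology", "physiology", "questionnaire")
  if (!all(catalog$type %in% ok_type)) abort("unknown score type.")
  attr(catalog, "total_variables") <- sum(catalog$n_variables)
  class(catalog) <- c("score_catalog", class(catalog))
  catalog
}

#' Default life-span neurobehavioral score catalog
#'
#' The 23-entry battery of neuropsychological, physiological and
#' questionnaire measures used for brain-age delta profiling in life-span
#' cohorts (Cam-CAN-style), enumerating 38 variables in total.
#'
#' @return A `score_catalog` (see [build_score_catalog()]).
#' @export
default_score_catalog <- function() {
  build_score_catalog(tibble(
    name = c("benton_faces", "emotional_expression_recognition",
             "emotional_memory", "emotion_regulation", "famous_faces",
             "fluid_intelligence", "force_matching", "hotel_task",
             "motor_learning", "picture_priming", "proverb_comprehension",
             "rt_choice", "rt_simple", "sentence_comprehension",
             "tip_of_the_tongue", "visual_short_term_memory",
             "cardio_markers", "psqi", "hours_slept", "hads_depression",
             "hads_anxiety", "ace_r", "mmse"),
    type = c(rep("neuropsychology", 16L), "physiology",
             rep("questionnaire", 6L)),
    aggregation = c("total", "PC1", "PC1", "mean", "ratio", "total",
                    "difference", "total", "mean", "mean", "total", "mean",
                    "mean", "mean", "ratio", "mean", "total", "total",
                    "total", "total", "total", "total", "total"),
    n_variables = c(1L, 1L, 3L, 3L, 1L, 1L, 2L, 1L, 2L, 4L, 1L, 1L, 1L,
                    2L, 1L, 4L, 3L, 1L, 1L, 1L, 1L, 1L, 1L)))
}

#' Aggregate sub-scores into a catalog score
#'
#' Supports totals (row sums), means, ratios (first/second), differences
#' (first - second) and the first principal component of the standardized
#' sub-scores (sign fixed so the largest-magnitude loading is positive;
#' the explained-variance ratio is attached as an attribute).
#'
#' @param sub_scores Subjects x sub-scores numeric matrix or data frame.
#' @param aggregation One of `"total"`, `"mean"`, `"ratio"`,
#'   `"difference"`, `"PC1"`.
#' @return Numeric vector of aggregated scores.
#' @export
aggregate_score <- function(sub_scores,
                            aggregation = c("total", "mean", "ratio",
                                            "difference", "PC1")) {
  aggregation <- match.arg(aggregation)
  m <- as.matrix(sub_scores)
  switch(aggregation,
    total = rowSums(m),
    mean = rowMeans(m),
    ratio = {
      if (ncol(m) != 2L) abort("ratio needs exactly 2 sub-scores.")
      m[, 1L] / m[, 2L]
    },
    difference = {
      if (ncol(m) != 2L) abort("difference needs exactly 2 sub-scores.")
      m[, 1L] - m[, 2L]
    },
    PC1 = {
      pc <- prcomp(m, center = TRUE, scale. = TRUE)
      load <- pc$rotation[, 1L]
      sign_fix <- sign(load[which.max(abs(load))])
      scores <- pc$x[, 1L] * sign_fix
      attr(scores, "explained_variance") <-
        pc$sdev[1L]^2 / sum(pc$sdev^2)
      scores
    })
}
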