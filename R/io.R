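# Table and config I/O. Tab-delimited tables with '#'-prefixed metadata
# header lines (diff-friendly); missing token "NA" at the I/O boundary,
# sentinel substitution happens only inside double_code().

#' Read a feature-block table
#'
#' Expects delimited text with a header row and `subject_id` as the first
#' column; `#`-prefixed lines are metadata comments.
#'
#' @param path File path.
#' @param missing_token Token parsed as missing (flagged, never as 0).
#' @param delim Field delimiter (default tab).
#' @return List with `matrix` (numeric, rownames = subject ids) and
#'   `subject_ids`.
#' @export
read_block_table <- function(path, missing_token = "NA", delim = "\t") {
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          na = missing_token, show_col_types = FALSE)
  if (names(df)[1L] != "subject_id") {
    abort("first column must be `subject_id`.")
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) abort("duplicate subject_id values.")
  vals <- df[-1L]
  bad <- !vapply(vals, is.numeric, TRUE)
  if (any(bad)) {
    abort(sprintf("non-numeric cells in column(s): %s.",
                  paste(names(vals)[bad], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  list(matrix = m, subject_ids = ids)
}

#' Write a feature-block table
#'
#' @param x Numeric matrix (subjects x features).
#' @param subject_ids Subject identifiers (defaults to rownames).
#' @param path Output path.
#' @param comments Character vector written as `#`-prefixed header lines
#'   (e.g. the config hash).
#' @return `path`, invisibly.
#' @export
write_block_table <- function(x, path, subject_ids = rownames(x),
                              comments = character()) {
  df <- tibble(subject_id = subject_ids)
  df <- dplyr::bind_cols(df, as_tibble(as.data.frame(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(col)] <- "NA"
    out
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read/write a run configuration
#'
#' Configurations are structured JSON (nested key/value). [read_run_config()]
#' validates that referenced input files exist.
#'
#' @param config Named list.
#' @param path File path.
#' @return The config list (read) or `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("block_paths", "age_path", "score_path")) {
    for (p in unlist(config[[key]])) {
      if (!file.exists(p)) abort(sprintf("referenced file missing: %s", p))
    }
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

default_run_config <- function() {
  list(
    seed = 1L,
    n_subjects = 200L,
    age_range = c(18, 88),
    blocks = list(
      list(name = "meg", n_features = 30L, noise_sd = 2,
           missingness = "MCAR", miss_rate = 0.1),
      list(name = "fmri", n_features = 30L, noise_sd = 2,
           missingness = "none", miss_rate = 0),
      list(name = "mri", n_features = 30L, noise_sd = 2,
           missingness = "none", miss_rate = 0)),
    scores = list(
      list(name = "fluid_intelligence", age_poly_coefs = c(-0.5),
           health_loading = 0.3, noise_sd = 1)),
    cv = list(n_folds = 10L, n_repeats = 2L),
    forest = list(n_trees = 200L),
    sentinels = c(-1000, 1000))
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order: `simulate` -> `stack` ->
#' `evaluate` -> `importance` -> `delta`, writing tab-delimited outputs
#' (each carrying the config hash in a comment header) and a structured
#' run manifest. Later stages require their dependencies among the
#' requested stages.
#'
#' @param config Nested config list (see `write_run_config()`); anything
#'   omitted falls back to a small default synthetic run.
#' @param stages Character vector of stages to execute.
#' @param output_dir Output directory (created if needed).
#' @return A `run_manifest`: config hash, package version, per-stage
#'   timestamps and per-file md5 checksums. Deterministic stages yield
#'   identical checksums when rerun with an identical config.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "stack", "evaluate",
                                    "importance", "delta"),
                         output_dir = tempfile("oppstack_run")) {
  known <- c("simulate", "stack", "evaluate", "importance", "delta")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(sprintf("unknown stage name(s): %s.", paste(bad, collapse = ", ")))
  }
  deps <- list(stack = "simulate", evaluate = "stack",
               importance = "stack", delta = "stack")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      abort(sprintf("stage '%s' requires stage '%s'.", s, need))
    }
  }
  config <- utils::modifyList(default_run_config(), config)
  hash <- config_hash(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("config_hash %s", hash),
           sprintf("seed %d", config$seed))
  manifest <- list(config_hash = hash,
                   version = as.character(utils::packageVersion("oppstack")),
                   stages = list())
  outputs <- character()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    files <- fun()
    manifest$stages[[name]] <<- list(
      started = format(t0, "%Y-%m-%dT%H:%M:%OS3"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
    outputs <<- c(outputs, files)
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- simulation_config(
        n_subjects = config$n_subjects, age_range = config$age_range,
        block_specs = lapply(config$blocks, function(b) {
          do.call(block_spec, b)
        }),
        score_specs = lapply(config$scores, function(s) {
          do.call(score_spec, s)
        }),
        seed = config$seed)
      state$dataset <- simulate_multimodal(cfg)
      state$scores <- simulate_scores(state$dataset)
      files <- character()
      for (b in names(state$dataset$blocks)) {
        x <- state$dataset$blocks[[b]]
        x[!state$dataset$masks[[b]], ] <- NA
        f <- file.path(output_dir, sprintf("block_%s.tsv", b))
        write_block_table(x, f, comments = hdr)
        files <- c(files, f)
      }
      f <- file.path(output_dir, "age.tsv")
      write_block_table(cbind(age = state$dataset$subjects$age), f,
                        subject_ids = state$dataset$subjects$subject_id,
                        comments = hdr)
      mask <- do.call(cbind, state$dataset$masks) * 1L
      fm <- file.path(output_dir, "mask.tsv")
      write_block_table(mask, fm,
                        subject_ids = state$dataset$subjects$subject_id,
                        comments = hdr)
      c(files, f, fm)
    })
  }
  if ("stack" %in% stages) {
    run_stage("stack", function() {
      cv <- cv_scheme(nrow(state$dataset$subjects),
                      n_folds = config$cv$n_folds,
                      n_repeats = config$cv$n_repeats, seed = config$seed)
      fspec <- do.call(forest_spec, config$forest)
      state$model <- opportunistic_stack(
        state$dataset, cv, forest = fspec,
        sentinels = config$sentinels, seed = config$seed)
      f <- file.path(output_dir, "predictions.tsv")
      cp <- consensus_predictions(state$model)
      write_block_table(as.matrix(cp[-1L]), f, subject_ids = cp$subject_id,
                        comments = hdr)
      f2 <- file.path(output_dir, "hyperparameters.tsv")
      readr::write_tsv(dplyr::left_join(
        state$model$tuned,
        state$model$stacked_predictions$lambdas,
        by = "rep", relationship = "many-to-many"), f2)
      c(f, f2)
    })
  }
  if ("evaluate" %in% stages) {
    run_stage("evaluate", function() {
      f <- file.path(output_dir, "fold_scores.tsv")
      dummy <- dummy_fold_scores(state$model$age, state$model$cv)
      readr::write_tsv(dplyr::bind_rows(
        as_tibble(state$model$fold_scores), as_tibble(dummy)), f)
      f2 <- file.path(output_dir, "model_comparison.tsv")
      readr::write_tsv(paired_compare(state$model$fold_scores, dummy), f2)
      c(f, f2)
    })
  }
  if ("importance" %in% stages) {
    run_stage("importance", function() {
      coded <- double_code(state$model$stacked_predictions,
                           sentinels = state$model$sentinels, repeat_ = 1L)
      imp <- permutation_importance(state$model$forests[[1L]], coded,
                                    state$model$age, k = 25L,
                                    seed = config$seed)
      imp$mdi <- mdi_importance(state$model$forests[[1L]])$importance
      f <- file.path(output_dir, "importance.tsv")
      readr::write_tsv(imp, f)
      f
    })
  }
  if ("delta" %in% stages) {
    run_stage("delta", function() {
      cp <- consensus_predictions(state$model)
      assoc <- delta_association_table(
        state$scores, cp$delta, cp$age)
      f <- file.path(output_dir, "delta_associations.tsv")
      readr::write_tsv(assoc, f)
      f
    })
  }

  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  manifest$output_dir <- output_dir
  write_run_config(manifest, file.path(output_dir, "manifest.json"))
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d stages, config %s\n", length(x$stages),
              x$config_hash))
  for (s in names(x$stages)) cat("  stage:", s, "\n")
  invisible(x)
}

#' Assemble a multimodal dataset from block tables on disk
#'
#' @param block_paths Named character vector of block-table paths.
#' @param age_path Path to a table with `subject_id` and `age` columns.
#' @return A `multimodal_dataset`; rows absent from a block (or all-NA)
#'   are marked unavailable in its mask.
#' @export
read_multimodal <- function(block_paths, age_path) {
  age_tab <- read_block_table(age_path)
  ids <- age_tab$subject_ids
  age <- as.numeric(age_tab$matrix[, 1L])
  blocks <- list()
  masks <- list()
  for (b in names(block_paths)) {
    tab <- read_block_table(block_paths[[b]])
    m <- matrix(NA_real_, nrow = length(ids), ncol = ncol(tab$matrix),
                dimnames = list(ids, colnames(tab$matrix)))
    common <- intersect(ids, tab$subject_ids)
    m[common, ] <- tab$matrix[common, , drop = FALSE]
    mask <- !apply(m, 1L, anyNA)
    blocks[[b]] <- m
    masks[[b]] <- unname(mask)
  }
  if (any(Reduce(`+`, masks) == 0)) {
    abort("subject(s) with no observed block; drop them before stacking.")
  }
  structure(list(subjects = tibble(subject_id = ids, age = age,
                                   health = NA_real_),
                 blocks = blocks, masks = masks, config = NULL),
            class = "multimodal_dataset")
}
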