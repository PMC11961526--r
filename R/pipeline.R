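#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class ordering (default: sorted union).
#' @return K x K integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  table(factor(truth, levels = classes),
        factor(predicted, levels = classes))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total; balanced accuracy the unweighted
#' mean of per-class recalls (classes without support excluded); macro F1
#' the unweighted mean of per-class F1 scores, with a class's F1 set to 0
#' when its precision and recall are both undefined or zero. All metrics
#' are reported in percent.
#'
#' @param cm Square nonnegative count matrix (rows = truth).
#' @return List with `accuracy`, `balanced_accuracy`, `macro_f1`, each in
#'   \[0, 100\].
#' @examples
#' classification_metrics(matrix(c(9, 4, 1, 6), 2)) # 75 / 75 / ~74.4
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("confusion matrix must be square with at least one observation")
  }
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  support <- rowSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
  bal <- mean(recall, na.rm = TRUE)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, diag(cm) / predicted, 0)
  rec0 <- ifelse(support > 0, diag(cm) / support, 0)
  f1 <- ifelse(precision + rec0 > 0,
               2 * precision * rec0 / (precision + rec0), 0)
  list(accuracy = 100 * acc, balanced_accuracy = 100 * bal,
       macro_f1 = 100 * mean(f1))
}

# ecotype/variety target: 3 classes (or 2 with collapse_varieties)
.ecotype_class <- function(spec, n_classes = 3) {
  if (n_classes == 3) {
    ifelse(spec$ecotype == "fennicus", "fennicus",
           paste(spec$variety, "tarandus"))
  } else {
    spec$ecotype
  }
}

.one_cell <- function(feats, class, strata, seed, grid, k_folds, priors,
                      positive_class = NULL) {
  plan <- withCallingHandlers(
    stratified_split(strata, test_fraction = 0.2,
                     seed = rng_substream(seed, "split")),
    warning = function(w) invokeRestart("muffleWarning")
  )
  x <- feats$features
  tr <- plan$train
  te <- plan$test
  if (length(unique(class[tr])) < 2L || length(te) == 0L) {
    stop("degenerate split: a class is absent from train or test is empty")
  }
  tuned <- tune_rda(x[tr, , drop = FALSE], class[tr], grid = grid,
                    k = k_folds, seed = rng_substream(seed, "cv"),
                    priors = priors)
  fit <- fit_rda(x[tr, , drop = FALSE], class[tr],
                 lambda = tuned$lambda, gamma = tuned$gamma, priors = priors)
  classes <- sort(unique(class))
  row_for <- function(idx, partition) {
    pred <- predict_rda(fit, x[idx, , drop = FALSE])
    cm <- confusion_matrix(class[idx], pred$labels, classes = classes)
    mt <- classification_metrics(cm)
    extra_f1 <- NA_real_
    if (!is.null(positive_class) && positive_class %in% classes) {
      j <- match(positive_class, classes)
      tp <- cm[j, j]; fp <- sum(cm[-j, j]); fn <- sum(cm[j, -j])
      extra_f1 <- if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else 0
    }
    tibble::tibble(
      element = feats$element, subset_id = feats$subset_id,
      partition = partition, n = length(idx),
      accuracy = mt$accuracy, balanced_accuracy = mt$balanced_accuracy,
      macro_f1 = mt$macro_f1, positive_f1 = extra_f1,
      lambda = tuned$lambda, gamma = tuned$gamma, seed = seed,
      confusion = list(cm)
    )
  }
  dplyr::bind_rows(row_for(tr, "train"), row_for(te, "test"))
}

#' Ecotype/variety classification experiment
#'
#' For each element and variable subset: build the complete-case matrix,
#' compute isometric-size and log-shape-ratio features, split 80/20
#' stratified by ecotype/variety and sex, tune the RDA hyperparameters by
#' stratified tenfold cross-validation on the training part, fit, and
#' report train and test metrics. The target has three classes (domestic
#' tarandus, wild tarandus, fennicus); `n_classes = 2` collapses the
#' tarandus varieties. The pelvis and the tiny wild-male group are
#' excluded by default.
#'
#' @param tab Specimen tibble (validated; inclusion rules and side dedup
#'   are the caller's responsibility, see [apply_inclusion_rules()]).
#' @param elements Elements to process (default the six long bones).
#' @param subsets Variable subset ids (default all five).
#' @param registry Measurement registry.
#' @param seed Top-level integer seed; split, fold, and tuning randomness
#'   derive from it via named substreams.
#' @param grid Hyperparameter grid (see [default_rda_grid()]).
#' @param k_folds Cross-validation folds (default 10).
#' @param priors Prior specification for [fit_rda()].
#' @param n_classes 3 (default) or 2.
#' @param include_wild_male Keep the wild-male group (default `FALSE`).
#' @return An `eval_report` tibble: one train and one test row per
#'   element x subset processed, with metrics in percent, selected
#'   hyperparameters, and the confusion matrix as a list column. Cells
#'   that cannot be processed (too few specimens or classes) are skipped
#'   with a warning.
#' @export
run_ecotype_experiment <- function(tab,
                                   elements = setdiff(osteo_elements(), "pelvis"),
                                   subsets = c("all", "proximal", "distal",
                                               "shaft", "complete_reduced"),
                                   registry = measurement_registry(),
                                   seed = 1L,
                                   grid = default_rda_grid(),
                                   k_folds = 10,
                                   priors = "empirical",
                                   n_classes = 3,
                                   include_wild_male = FALSE) {
  tab <- assign_groups(tab)
  if (!include_wild_male) tab <- tab[tab$group != 4L, , drop = FALSE]
  rows <- list()
  for (el in elements) {
    for (sb in subsets) {
      res <- tryCatch({
        m <- select_matrix(tab, el, sb, registry = registry)
        feats <- size_shape_features(m)
        class <- .ecotype_class(feats$specimens, n_classes)
        strata <- paste(class, feats$specimens$sex)
        .one_cell(feats, class, strata,
                  seed = rng_substream(seed, paste(el, sb)),
                  grid = grid, k_folds = k_folds, priors = priors)
      }, error = function(e) {
        warning("skipping ", el, "/", sb, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Castrate detection experiment (one-vs-rest)
#'
#' Relabels specimens as `castrate` vs `rest` and runs the same split /
#' tune / fit / evaluate machinery as the ecotype experiment. Reports
#' the binary metrics with the castrate class's F1 in `positive_f1`.
#'
#' @inheritParams run_ecotype_experiment
#' @param min_castrates Minimum castrate count required (default 5).
#' @return An `eval_report` tibble (train and test rows per cell).
#' @export
run_castrate_detection <- function(tab,
                                   elements = setdiff(osteo_elements(), "pelvis"),
                                   subsets = c("all", "proximal", "distal",
                                               "shaft", "complete_reduced"),
                                   registry = measurement_registry(),
                                   seed = 1L,
                                   grid = default_rda_grid(),
                                   k_folds = 10,
                                   priors = "empirical",
                                   include_wild_male = FALSE,
                                   min_castrates = 5) {
  tab <- assign_groups(tab)
  if (!include_wild_male) tab <- tab[tab$group != 4L, , drop = FALSE]
  if (sum(tab$castrated) < min_castrates) {
    stop("too few castrated specimens (", sum(tab$castrated),
         " < ", min_castrates, ") for one-vs-rest detection")
  }
  rows <- list()
  for (el in elements) {
    for (sb in subsets) {
      res <- tryCatch({
        m <- select_matrix(tab, el, sb, registry = registry)
        feats <- size_shape_features(m)
        class <- ifelse(feats$specimens$castrated, "castrate", "rest")
        if (sum(class == "castrate") < min_castrates) {
          stop("fewer than ", min_castrates, " castrates with complete data")
        }
        .one_cell(feats, class, strata = class,
                  seed = rng_substream(seed, paste(el, sb)),
                  grid = grid, k_folds = k_folds, priors = priors,
                  positive_class = "castrate")
      }, error = function(e) {
        warning("skipping ", el, "/", sb, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Write an evaluation report to disk
#'
#' Emits the report as CSV (numeric columns only; confusion matrices are
#' flattened into a companion file) and as a human-readable fixed-width
#' table (Element, Variable set, Train/Test, Accuracy, Balanced accuracy,
#' F1-measure). F1 is macro-averaged; that convention is recorded in the
#' text header.
#'
#' @param report `eval_report` tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- dplyr::select(report, -"confusion")
  csv_path <- file.path(dir, "classification_report.csv")
  readr::write_csv(flat, csv_path)
  cm_rows <- list()
  for (i in seq_len(nrow(report))) {
    cm <- as.matrix(report$confusion[[i]])
    cm_rows[[i]] <- tibble::tibble(
      element = report$element[i], subset_id = report$subset_id[i],
      partition = report$partition[i],
      truth = rep(rownames(cm), times = ncol(cm)),
      predicted = rep(colnames(cm), each = nrow(cm)),
      count = as.vector(cm)
    )
  }
  cm_path <- file.path(dir, "confusion_matrices.csv")
  readr::write_csv(dplyr::bind_rows(cm_rows), cm_path)
  txt_path <- file.path(dir, "classification_report.txt")
  hdr <- sprintf("%-12s %-18s %-6s %9s %18s %11s",
                 "Element", "Variable set", "Part.",
                 "Accuracy", "Balanced accuracy", "F1-measure")
  lines <- c("Correct classification rates (percent; F1 macro-averaged)",
             hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf(
      "%-12s %-18s %-6s %9.1f %18.1f %11.1f",
      report$element[i], report$subset_id[i],
      ifelse(report$partition[i] == "train", "Train", "Test"),
      report$accuracy[i], report$balanced_accuracy[i], report$macro_f1[i]))
  }
  writeLines(lines, txt_path)
  invisible(c(csv = csv_path, confusion = cm_path, text = txt_path))
}
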