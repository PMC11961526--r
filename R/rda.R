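# round-half-up, as opposed to base R's banker's rounding
round_half_up <- function(x) floor(x + 0.5)

# deterministic 32-bit sub-seed for a named random substream
rng_substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Stratified train/test split
#'
#' Splits specimens into train and test sets so that each stratum (e.g.
#' the interaction of ecotype/variety and sex) contributes its share of
#' test members: round-half-up of `n * test_fraction`, with a floor of one
#' test member for strata of at least 5. Strata smaller than 5 go entirely
#' to training with a warning (their test share would be statistically
#' meaningless); singleton strata warn likewise, or error when
#' `small_strata = "error"`.
#'
#' @param strata Character/factor vector, one entry per specimen.
#' @param test_fraction Target test share (default 0.2, the 80/20 split).
#' @param seed Integer seed; identical seeds give identical plans.
#' @param small_strata `"warn"` (default) or `"error"`.
#' @return An object of class `split_plan`: list with integer index
#'   vectors `train`, `test`, plus `strata`, `test_fraction`, `seed`.
#'   Train and test are disjoint and exhaustive.
#' @export
stratified_split <- function(strata, test_fraction = 0.2, seed = 1L,
                             small_strata = c("warn", "error")) {
  small_strata <- match.arg(small_strata)
  stopifnot(test_fraction > 0, test_fraction < 1)
  strata <- as.character(strata)
  idx_test <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (s in sort(unique(strata))) {
      members <- which(strata == s)
      n <- length(members)
      if (n < 5L) {
        msg <- paste0("stratum '", s, "' has ", n,
                      " member(s); placed entirely in train")
        if (small_strata == "error" && n < 2L) stop(msg)
        warning(msg)
        next
      }
      n_test <- max(1L, round_half_up(n * test_fraction))
      idx_test <- c(idx_test, sample(members, n_test))
    }
  })
  idx_test <- sort(idx_test)
  structure(
    list(train = setdiff(seq_along(strata), idx_test), test = idx_test,
         strata = strata, test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Fit a regularized discriminant analysis model
#'
#' Gaussian discriminant classifier with Friedman-style two-parameter
#' covariance regularization. Per class `k` the sample covariance is first
#' blended toward the pooled covariance,
#' `S_k(lambda) = (1 - lambda) S_k + lambda S_pooled`, then shrunk toward
#' a scaled identity,
#' `S_k(lambda, gamma) = (1 - gamma) S_k(lambda) + gamma (tr(S_k(lambda)) / p) I`.
#' `lambda = 0, gamma = 0` is QDA; `lambda = 1, gamma = 0` is LDA;
#' `gamma = 1` gives spherical (nearest-mean-like) class covariances.
#'
#' @param x Numeric feature matrix (specimens in rows).
#' @param y Class labels (>= 2 classes, each with >= 2 members).
#' @param lambda,gamma Regularization weights in \[0,1\].
#' @param priors `"empirical"` (class frequencies, default), `"uniform"`,
#'   or a named numeric vector summing to 1.
#' @return An object of class `rda_model` storing class labels, means,
#'   raw and regularized covariances, pooled covariance, hyperparameters,
#'   priors, and the feature column names.
#' @export
fit_rda <- function(x, y, lambda = 1, gamma = 0, priors = "empirical") {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y),
            lambda >= 0, lambda <= 1, gamma >= 0, gamma <= 1)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_k <- table(factor(y, levels = classes))
  if (any(n_k < 2L)) {
    stop("each class needs >= 2 specimens; too small: ",
         paste(classes[n_k < 2], collapse = ", "))
  }
  p <- ncol(x)
  means <- lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))
  names(means) <- classes
  covs <- lapply(classes, function(k) stats::cov(x[y == k, , drop = FALSE]))
  names(covs) <- classes
  pooled <- Reduce(`+`, Map(function(S, nk) S * (nk - 1), covs, as.list(as.numeric(n_k))))
  pooled <- pooled / (nrow(x) - length(classes))
  reg <- lapply(covs, function(S) {
    Sl <- (1 - lambda) * S + lambda * pooled
    (1 - gamma) * Sl + gamma * (sum(diag(Sl)) / p) * diag(p)
  })
  # Cholesky factors up front: fails fast on singular covariances
  chols <- vector("list", length(classes))
  names(chols) <- classes
  for (k in classes) {
    ch <- tryCatch(chol(reg[[k]]), error = function(e) NULL)
    # exact or near collinearity can slip through chol numerically
    if (!is.null(ch) && min(diag(ch)) < 1e-6 * max(diag(ch))) {
      ch <- NULL
    }
    if (is.null(ch)) {
      stop("regularized covariance for class '", k, "' is singular; ",
           "increase gamma or drop one shape component")
    }
    chols[[k]] <- ch
  }
  pri <- if (identical(priors, "empirical")) {
    as.numeric(n_k) / length(y)
  } else if (identical(priors, "uniform")) {
    rep(1 / length(classes), length(classes))
  } else {
    if (!setequal(names(priors), classes)) stop("priors must be named by class")
    pv <- as.numeric(priors[classes])
    if (any(pv <= 0)) stop("priors must be positive")
    pv / sum(pv)
  }
  names(pri) <- classes
  structure(
    list(classes = classes, means = means, covariances = covs,
         pooled = pooled, reg_covariances = reg, chol = chols,
         lambda = lambda, gamma = gamma, priors = pri,
         feature_names = colnames(x), n_per_class = as.numeric(n_k)),
    class = "rda_model"
  )
}

#' Predict with an RDA model
#'
#' Scores each specimen against each class with the Gaussian discriminant
#' `d_k(x) = -0.5 log det(S_k) - 0.5 (x - mu_k)' S_k^{-1} (x - mu_k) + log pi_k`,
#' assigns the argmax label (ties to the lowest class index), and returns
#' posteriors as the softmax of the scores (rows sum to 1).
#'
#' @param model `rda_model`.
#' @param x Feature matrix with the model's columns.
#' @return List with `labels` (character), `posterior` (matrix, one
#'   column per class), `scores` (discriminant score matrix).
#' @export
predict_rda <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$means[[1]])) {
    stop("feature dimension mismatch: model has ",
         length(model$means[[1]]), ", data has ", ncol(x))
  }
  n <- nrow(x)
  K <- length(model$classes)
  scores <- matrix(NA_real_, n, K, dimnames = list(NULL, model$classes))
  for (j in seq_len(K)) {
    k <- model$classes[j]
    ch <- model$chol[[k]]
    logdet <- 2 * sum(log(diag(ch)))
    centered <- sweep(x, 2, model$means[[k]])
    # Mahalanobis via triangular solve against the Cholesky factor
    z <- backsolve(ch, t(centered), transpose = TRUE)
    maha <- colSums(z^2)
    scores[, j] <- -0.5 * logdet - 0.5 * maha + log(model$priors[[k]])
  }
  shifted <- scores - apply(scores, 1, max)
  post <- exp(shifted)
  post <- post / rowSums(post)
  labels <- model$classes[apply(scores, 1, which.max)]
  list(labels = labels, posterior = post, scores = scores)
}

#' @export
print.rda_model <- function(x, ...) {
  cat("rda_model:", length(x$classes), "classes x",
      length(x$means[[1]]), "features | lambda =", x$lambda,
      "gamma =", x$gamma, "\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# stratified fold assignment: within each class, shuffled then dealt
# cyclically across folds
.cv_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in sort(unique(y))) {
      members <- which(y == cl)
      members <- members[sample.int(length(members))]
      folds[members] <- rep_len(seq_len(k), length(members))
    }
  })
  folds
}

#' Tune RDA hyperparameters by stratified k-fold cross-validation
#'
#' Evaluates every `(lambda, gamma)` grid point with stratified k-fold
#' cross-validation (default tenfold) on the training data and selects
#' the point with the highest mean balanced accuracy; ties break toward
#' more regularization (larger lambda, then larger gamma). When `k`
#' exceeds the smallest class size it is reduced with a warning.
#'
#' @param x Training feature matrix.
#' @param y Training labels.
#' @param grid Data frame with columns `lambda`, `gamma` (default the
#'   5 x 5 grid lambda in \{0, .25, .5, .75, 1\} x gamma in
#'   \{0, .1, .25, .5, 1\}).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param priors Passed to [fit_rda()].
#' @return List with `lambda`, `gamma` (the selection), and `cv_table`
#'   (tibble: grid point, mean balanced accuracy, mean accuracy, mean
#'   macro F1, in percent).
#' @export
tune_rda <- function(x, y, grid = default_rda_grid(), k = 10, seed = 1L,
                     priors = "empirical") {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  min_class <- min(table(y))
  if (k > min_class) {
    warning("k = ", k, " exceeds smallest class size; reduced to ", min_class)
    k <- min_class
  }
  folds <- .cv_folds(y, k, seed)
  res <- list()
  for (i in seq_len(nrow(grid))) {
    ba <- acc <- f1 <- numeric(0)
    for (f in seq_len(k)) {
      tr <- folds != f
      te <- !tr
      if (length(unique(y[tr])) < 2L || !any(te)) next
      fit <- tryCatch(
        fit_rda(x[tr, , drop = FALSE], y[tr],
                lambda = grid$lambda[i], gamma = grid$gamma[i],
                priors = priors),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      pred <- predict_rda(fit, x[te, , drop = FALSE])
      cm <- confusion_matrix(y[te], pred$labels, classes = sort(unique(y)))
      mt <- classification_metrics(cm)
      ba <- c(ba, mt$balanced_accuracy)
      acc <- c(acc, mt$accuracy)
      f1 <- c(f1, mt$macro_f1)
    }
    res[[i]] <- tibble::tibble(
      lambda = grid$lambda[i], gamma = grid$gamma[i],
      n_folds = length(ba),
      balanced_accuracy = if (length(ba)) mean(ba) else NA_real_,
      accuracy = if (length(acc)) mean(acc) else NA_real_,
      macro_f1 = if (length(f1)) mean(f1) else NA_real_
    )
  }
  cv <- dplyr::bind_rows(res)
  ok <- which(!is.na(cv$balanced_accuracy))
  if (!length(ok)) stop("no grid point could be evaluated")
  # best balanced accuracy; ties -> larger lambda, then larger gamma
  best <- ok[order(-cv$balanced_accuracy[ok], -cv$lambda[ok], -cv$gamma[ok])][1]
  list(lambda = cv$lambda[best], gamma = cv$gamma[best], cv_table = cv)
}

#' Default RDA hyperparameter grid
#'
#' Spans QDA (`lambda = 0`) through LDA (`lambda = 1`) and spherical
#' shrinkage (`gamma = 1`).
#'
#' @return Data frame with columns `lambda`, `gamma`.
#' @export
default_rda_grid <- function() {
  expand.grid(lambda = c(0, 0.25, 0.5, 0.75, 1),
              gamma = c(0, 0.1, 0.25, 0.5, 1))
}

#' Serialize an RDA model to a JSON-compatible list
#'
#' @param model `rda_model`.
#' @return A plain list (matrices as row-major nested lists) suitable for
#'   `jsonlite::write_json()`.
#' @export
rda_model_to_list <- function(model) {
  list(
    classes = model$classes,
    feature_names = model$feature_names,
    lambda = model$lambda, gamma = model$gamma,
    priors = as.list(model$priors),
    means = lapply(model$means, unname),
    reg_covariances = lapply(model$reg_covariances,
                             function(S) apply(unname(S), 1, as.list))
  )
}
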