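# Train/test splitting, baseline classifiers (SVM, LASSO logistic
# regression), evaluation metrics, and the end-to-end classification
# pipeline over a cohort: measurements -> RR correction -> subject features
# -> optional PCA -> classifier -> sensitivity/specificity/accuracy.

#' Stratified train/test split of subjects
#'
#' Randomly assigns a fraction of each class's subjects to the training
#' set, the remainder to the test set; seeded and reproducible.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param labels Factor/character class labels aligned with `subject_ids`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(subject_ids, labels, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_ecg("fraction must lie strictly between 0 and 1")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop_ecg("two classes are required")
  if (any(table(labels) < 2))
    stop_ecg("each class needs at least 2 subjects to split")
  set.seed(as.integer(seed))
  train <- unlist(lapply(levels(labels), function(cl) {
    ids <- subject_ids[labels == cl]
    n_tr <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
    sample(ids, n_tr)
  }), use.names = FALSE)
  list(train = train, test = setdiff(subject_ids, train))
}

#' Train the SVM baseline
#'
#' Radial-kernel support vector machine (libsvm via e1071) with cost and
#' gamma chosen by 5-fold cross-validated accuracy on the training set;
#' the search and folds are seeded.
#'
#' @param x Numeric training matrix.
#' @param y Class factor.
#' @param cost_grid,gamma_scale Hyperparameter search: costs tried, and
#'   multipliers of the default gamma `1/ncol(x)`.
#' @param seed Integer RNG seed.
#' @return An `e1071::svm` fit with the chosen hyperparameters recorded
#'   in attribute `"tuning"`.
#' @export
train_svm_baseline <- function(x, y, cost_grid = c(0.1, 1, 10, 100),
                               gamma_scale = c(0.25, 1, 4), seed = 1L) {
  y <- droplevels(as.factor(y))
  g0 <- 1 / ncol(x)
  grid <- expand.grid(cost = cost_grid, gamma = g0 * gamma_scale)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    set.seed(as.integer(seed))
    fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[i],
                      gamma = grid$gamma[i], cross = 5)
    fit$tot.accuracy
  }, 0)
  best <- which.max(acc)
  set.seed(as.integer(seed))
  fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best])
  attr(fit, "tuning") <- list(cost = grid$cost[best],
                              gamma = grid$gamma[best],
                              cv_accuracy = acc[best] / 100)
  fit
}

#' Train the LASSO logistic-regression baseline
#'
#' L1-penalized logistic regression (glmnet) with the penalty selected by
#' cross-validated binomial deviance at `lambda.min`; fold assignment is
#' seeded.
#'
#' @param x Numeric training matrix.
#' @param y Class factor (second level is modelled as the positive class).
#' @param nfolds Cross-validation folds.
#' @param seed Integer RNG seed.
#' @return A `cv.glmnet` fit.
#' @export
train_llr_baseline <- function(x, y, nfolds = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
  glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1, foldid = foldid)
}

#' Sensitivity, specificity and accuracy of predictions
#'
#' Disease is the positive class: sensitivity = TP / (TP + FN) over
#' diseased subjects, specificity = TN / (TN + FP) over healthy subjects,
#' accuracy = (TP + TN) / total.
#'
#' @param predictions,truth Aligned label vectors with levels
#'   `healthy` / `disease`.
#' @param method,feature_set Optional labels recorded in the report.
#' @return A `classification_report`: list with the 2x2 `confusion` table
#'   (truth in rows) and the three proportions.
#' @export
evaluate_predictions <- function(predictions, truth, method = NA,
                                 feature_set = NA) {
  lv <- c("healthy", "disease")
  predictions <- factor(as.character(predictions), levels = lv)
  truth <- factor(as.character(truth), levels = lv)
  if (length(predictions) != length(truth))
    stop_ecg("predictions and truth must have equal length")
  confusion <- table(truth = truth, predicted = predictions)
  tp <- confusion["disease", "disease"]; fn <- confusion["disease", "healthy"]
  tn <- confusion["healthy", "healthy"]; fp <- confusion["healthy", "disease"]
  structure(list(confusion = confusion,
                 sensitivity = unname(tp / (tp + fn)),
                 specificity = unname(tn / (tn + fp)),
                 accuracy = unname((tp + tn) / sum(confusion)),
                 method = method, feature_set = feature_set),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$feature_set, x$method)), collapse = " + ")
  cat("Classification report", if (nzchar(lab)) paste0(" [", lab, "]"),
      "\n", sep = "")
  print(x$confusion)
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

# median imputation fitted on training rows only
impute_by_train_median <- function(train, test) {
  med <- apply(train, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      bad <- !is.finite(m[, j])
      if (any(bad)) m[bad, j] <- med[j]
    }
    m
  }
  list(train = fill(train), test = fill(test))
}

#' Run the full classification procedure on a cohort
#'
#' Executes the pipeline end to end on a beat table: RR correction of the
#' time spans, per-subject feature summarization (quantile or mean),
#' stratified subject split, training-median imputation, optional PCA of
#' the numeric features (T-type proportions bypass the PCA and rejoin the
#' classifier input), classifier training and test-set evaluation.
#'
#' @param cohort A `synthetic_cohort` or beat table data frame.
#' @param feature_stat `"quantile"` (144 quantile features) or `"mean"`
#'   (18 beat-mean features); both carry the 6 T-type proportions.
#' @param use_pca Reduce numeric features to principal components first.
#' @param n_components Components kept when `use_pca = TRUE`.
#' @param method `"sda"`, `"svm"` or `"llr"`.
#' @param split_fraction Training fraction of subjects per class.
#' @param seed Integer seed controlling split and classifier randomness.
#' @param alphas RR-correction exponents (default [default_corrections()]).
#' @param min_beats Minimum usable beats per subject.
#' @param ... Further arguments passed to the classifier trainer.
#' @return A `classification_report` with the fitted `model` and the
#'   subject split attached.
#' @export
classify_cohort <- function(cohort, feature_stat = "quantile",
                            use_pca = TRUE, n_components = 8,
                            method = c("sda", "svm", "llr"),
                            split_fraction = 0.5, seed = 1L,
                            alphas = default_corrections(),
                            min_beats = 30, ...) {
  method <- match.arg(method)
  beats <- if (inherits(cohort, "synthetic_cohort")) cohort$beats else cohort
  beats <- adjust_beat_table(beats, alphas)
  fm <- build_feature_matrix(beats, stat = feature_stat,
                             min_beats = min_beats, impute = FALSE)
  sp <- split_train_test(rownames(fm$x), fm$y, fraction = split_fraction,
                         seed = seed)
  tr_i <- match(sp$train, rownames(fm$x))
  te_i <- match(sp$test, rownames(fm$x))
  imp <- impute_by_train_median(fm$x[tr_i, , drop = FALSE],
                                fm$x[te_i, , drop = FALSE])
  y_tr <- fm$y[tr_i]; y_te <- fm$y[te_i]

  num_cols <- setdiff(colnames(fm$x), fm$ttype_cols)
  if (use_pca) {
    pca <- suppressWarnings(fit_pca(imp$train[, num_cols, drop = FALSE]))
    pca <- select_components(pca, k = min(n_components,
                                          ncol(pca$loadings)))
    x_tr <- cbind(predict(pca, imp$train[, pca$feature_names, drop = FALSE]),
                  imp$train[, fm$ttype_cols, drop = FALSE])
    x_te <- cbind(predict(pca, imp$test[, pca$feature_names, drop = FALSE]),
                  imp$test[, fm$ttype_cols, drop = FALSE])
  } else {
    pca <- NULL
    x_tr <- imp$train; x_te <- imp$test
  }

  model <- switch(method,
    sda = train_sda(x_tr, y_tr, ...),
    svm = train_svm_baseline(x_tr, y_tr, seed = seed, ...),
    llr = train_llr_baseline(x_tr, y_tr, seed = seed, ...))
  pred <- switch(method,
    sda = predict(model, x_te),
    svm = predict(model, x_te),
    llr = factor(as.character(
            predict(model, x_te, s = "lambda.min", type = "class")),
          levels = levels(y_tr)))
  rep <- evaluate_predictions(pred, y_te, method = toupper(method),
                              feature_set = paste0(feature_stat,
                                                   if (use_pca) "+PCA"))
  rep$model <- model
  rep$pca <- pca
  rep$split <- sp
  rep
}

#' Compare feature sets and classifiers on one cohort
#'
#' Runs [classify_cohort()] over the cross of feature statistics
#' (mean/quantile), PCA on/off, and classification methods, returning one
#' row of test metrics per cell -- the standard 12-cell comparison design.
#'
#' @param cohort A `synthetic_cohort` or beat table.
#' @param methods Classifiers to include.
#' @param feature_stats Feature summaries to include.
#' @param use_pca PCA settings to include.
#' @param seed Seed shared by every cell (same split throughout).
#' @param ... Passed to [classify_cohort()].
#' @return Data frame with `feature_set`, `pca`, `method`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
run_comparison <- function(cohort, methods = c("sda", "svm", "llr"),
                           feature_stats = c("mean", "quantile"),
                           use_pca = c(FALSE, TRUE), seed = 1L, ...) {
  grid <- expand.grid(method = methods, pca = use_pca,
                      feature_set = feature_stats,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- classify_cohort(cohort, feature_stat = grid$feature_set[i],
                         use_pca = grid$pca[i], method = grid$method[i],
                         seed = seed, ...)
    data.frame(feature_set = grid$feature_set[i], pca = grid$pca[i],
               method = toupper(grid$method[i]),
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
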