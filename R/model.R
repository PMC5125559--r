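# Random-forest DTI classifier: training, grid search, cross-validation,
# evaluation and class-probability prediction.

#' Train the random-forest DTI classifier
#'
#' Fits a probability forest: the predicted positive-class probability of an
#' instance is the mean, over trees, of the fraction of positive training
#' samples in the leaf the instance falls into. Trees are fully grown.
#'
#' @param dataset A [encode_dataset()] / [synthetic_dti_dataset()] object.
#' @param n_trees Number of trees (default 150).
#' @param max_features Number of features considered at each split
#'   (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param importance Importance mode passed to the forest
#'   (`"impurity"` or `"permutation"`).
#' @return An object of class `dti_forest`.
#' @export
train_forest <- function(dataset, n_trees = 150, max_features = 100,
                         seed = 1L, importance = "impurity") {
  stopifnot(inherits(dataset, "dti_dataset"), n_trees >= 1)
  x <- dataset$features
  stopifnot(max_features >= 1, max_features <= ncol(x))
  y <- factor(dataset$labels, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) abort("training data must contain both classes")
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees, mtry = max_features,
    probability = TRUE, importance = importance,
    min.node.size = 1, # fully grown trees
    seed = seed, num.threads = 1
  )
  structure(list(
    forest = fit,
    feature_names = colnames(x),
    config = list(n_trees = n_trees, max_features = max_features, seed = seed)
  ), class = "dti_forest")
}

#' @export
print.dti_forest <- function(x, ...) {
  cat(sprintf("<dti_forest: %d trees, mtry %d, %d features>\n",
              x$config$n_trees, x$config$max_features, length(x$feature_names)))
  invisible(x)
}

#' Positive-class probabilities for a feature matrix
#'
#' @param model A [train_forest()] object.
#' @param features Numeric matrix whose columns match the model's feature
#'   names; a width or name mismatch is a hard error.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "dti_forest"))
  if (inherits(features, "dti_dataset")) features <- features$features
  if (ncol(features) != length(model$feature_names)) {
    abort(sprintf("feature width mismatch: model expects %d, got %d",
                  length(model$feature_names), ncol(features)))
  }
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), model$feature_names)) {
    abort("feature name manifest mismatch between model and data")
  }
  colnames(features) <- model$feature_names
  p <- predict(model$forest, data = features, num.threads = 1)$predictions
  unname(p[, "1"])
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    abort(sprintf("cannot build %d stratified folds: a class has too few members", k))
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# rank-based (Mann-Whitney) ROC AUC
roc_auc <- function(labels, probs) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = probs,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into `folds` stratified subsets, trains on all but one
#' and scores the held-out fold by ROC AUC, rotating through every fold.
#'
#' @inheritParams train_forest
#' @param folds Number of folds (default 5).
#' @return An object of class `dti_cv`: a list with `mean_auc` and a
#'   `fold_aucs` tibble.
#' @export
cross_validate <- function(dataset, n_trees = 150, max_features = 100,
                           folds = 5, seed = 1L) {
  stopifnot(inherits(dataset, "dti_dataset"), folds >= 2)
  fold_id <- stratified_folds(dataset$labels, folds, derive_seed(seed, "folds"))
  aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- subset_dataset(dataset, fold_id != f)
    te <- subset_dataset(dataset, fold_id == f)
    model <- train_forest(tr, n_trees, max_features, seed = derive_seed(seed, paste0("fold", f)))
    aucs[f] <- roc_auc(te$labels, predict_probability(model, te$features))
  }
  structure(list(
    mean_auc = mean(aucs),
    fold_aucs = tibble(fold = seq_len(folds), auc = aucs)
  ), class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("<dti_cv: mean AUC %.3f over %d folds>\n", x$mean_auc, nrow(x$fold_aucs)))
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  structure(list(
    records = dataset$records[idx, , drop = FALSE],
    features = dataset$features[idx, , drop = FALSE],
    labels = dataset$labels[idx]
  ), class = "dti_dataset")
}

#' Default hyperparameter grid
#'
#' `n_trees` in {50, 100, 150, 200} crossed with `max_features` in
#' {27 (about sqrt(755)), 50, 100, 150}.
#'
#' @return A tibble with columns `n_trees` and `max_features`.
#' @export
default_grid <- function() {
  tidyr::expand_grid(n_trees = c(50L, 100L, 150L, 200L),
                     max_features = c(27L, 50L, 100L, 150L))
}

#' Grid search over forest hyperparameters
#'
#' Scores every grid point by mean accuracy under stratified k-fold
#' cross-validation (the same fold assignment for every point) and returns
#' the winner. Ties are broken by fewer trees, then smaller `max_features`.
#'
#' @inheritParams cross_validate
#' @param grid A data frame with columns `n_trees`, `max_features`.
#' @return A list with `n_trees`, `max_features`, `accuracy`, and the full
#'   `results` tibble.
#' @export
grid_search <- function(dataset, grid = default_grid(), folds = 5, seed = 1L) {
  stopifnot(inherits(dataset, "dti_dataset"), nrow(grid) >= 1)
  if (length(unique(dataset$labels)) < 2) abort("grid search needs both classes")
  fold_id <- stratified_folds(dataset$labels, folds, derive_seed(seed, "grid-folds"))
  res <- grid
  res$accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- subset_dataset(dataset, fold_id != f)
      te <- subset_dataset(dataset, fold_id == f)
      model <- train_forest(tr, grid$n_trees[gi], grid$max_features[gi],
                            seed = derive_seed(seed, paste0("grid", gi, "fold", f)))
      p <- predict_probability(model, te$features)
      acc[f] <- mean(as.integer(p >= 0.5) == te$labels)
    }
    res$accuracy[gi] <- mean(acc)
  }
  ord <- order(-res$accuracy, res$n_trees, res$max_features)
  best <- res[ord[1], ]
  list(
    n_trees = best$n_trees[[1]],
    max_features = best$max_features[[1]],
    accuracy = best$accuracy[[1]],
    results = as_tibble(res)
  )
}

#' Evaluate a model on a labeled dataset
#'
#' Computes ROC AUC from the positive-class probabilities and a confusion
#' matrix at the given threshold (positive when probability >= threshold).
#'
#' @param model A [train_forest()] object.
#' @param dataset A labeled `dti_dataset` whose width matches the model.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `dti_evaluation` with fields `auc`, `tp`, `fp`,
#'   `fn`, `tn`, `threshold`, plus the probabilities and labels.
#' @export
evaluate <- function(model, dataset, threshold = 0.5) {
  stopifnot(inherits(dataset, "dti_dataset"))
  p <- predict_probability(model, dataset$features)
  y <- dataset$labels
  pred <- as.integer(p >= threshold)
  structure(list(
    auc = roc_auc(y, p),
    tp = sum(pred == 1 & y == 1),
    fp = sum(pred == 1 & y == 0),
    fn = sum(pred == 0 & y == 1),
    tn = sum(pred == 0 & y == 0),
    threshold = threshold,
    probabilities = p,
    labels = y
  ), class = "dti_evaluation")
}

#' @export
print.dti_evaluation <- function(x, ...) {
  cat(sprintf("<dti_evaluation: AUC %.3f | TP %d FP %d FN %d TN %d @ %.2f>\n",
              x$auc, x$tp, x$fp, x$fn, x$tn, x$threshold))
  invisible(x)
}

#' @export
tidy.dti_forest <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance))
}

#' @export
glance.dti_forest <- function(x, ...) {
  tibble(
    n_trees = x$config$n_trees,
    max_features = x$config$max_features,
    n_features = length(x$feature_names),
    oob_brier = x$forest$prediction.error
  )
}

#' @export
glance.dti_evaluation <- function(x, ...) {
  n <- x$tp + x$fp + x$fn + x$tn
  tibble(
    auc = x$auc, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    accuracy = (x$tp + x$tn) / n,
    sensitivity = if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA_real_,
    specificity = if (x$tn + x$fp > 0) x$tn / (x$tn + x$fp) else NA_real_,
    threshold = x$threshold, n = n
  )
}

#' @export
autoplot.dti_evaluation <- function(object, ...) {
  r <- pROC::roc(response = object$labels, predictor = object$probabilities,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  df <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  df <- arrange(df, .data$fpr, .data$tpr)
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(linetype = "dashed", color = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Save / load a trained model with its feature manifest
#'
#' The artifact is an RDS file accompanied by a JSON sidecar recording the
#' configuration, schema version and feature-name manifest. Loading verifies
#' the manifest and fails hard on mismatch.
#'
#' @param model A `dti_forest`.
#' @param path Output path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dti_forest"))
  saveRDS(model, path)
  sidecar <- list(
    schema_version = 1L,
    config = model$config,
    n_features = length(model$feature_names),
    feature_md5 = digest_vector(model$feature_names)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param manifest Expected feature names (default: the package manifest);
#'   `NULL` skips the check.
#' @export
load_model <- function(path, manifest = feature_manifest()$name) {
  model <- readRDS(path)
  if (!is.null(manifest) && !identical(model$feature_names, manifest)) {
    abort("model feature manifest does not match the expected manifest")
  }
  model
}

digest_vector <- function(x) {
  # stable fingerprint of a character vector without external digest packages
  s <- paste(x, collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%d:%d", nchar(s), as.integer(h))
}
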