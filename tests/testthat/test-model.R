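test_that("evaluation matches the hand-worked confusion matrix and AUC", {
  # labels 1,1,0,0 with probabilities .9,.4,.6,.1 at threshold .5:
  # TP=1, FN=1, FP=1, TN=1; rank-sum AUC = 3/4
  ev <- structure(list(
    auc = dtiscreen:::roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)),
    tp = 0, fp = 0, fn = 0, tn = 0
  ), class = "dti_evaluation")
  expect_equal(ev$auc, 0.75)

  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 30, max_features = 50, seed = 2)
  full <- evaluate(model, ds)
  expect_equal(full$tp + full$fp + full$fn + full$tn, length(ds$labels))
})

test_that("perfect and random probabilities give AUC 1 and about 0.5", {
  y <- rep(c(1, 0), each = 100)
  expect_equal(dtiscreen:::roc_auc(y, y), 1.0)
  p <- withr::with_seed(4, runif(200))
  expect_lt(abs(dtiscreen:::roc_auc(y, p) - 0.5), 0.12)
})

test_that("AUC is invariant to strictly monotone probability transforms", {
  y <- withr::with_seed(5, rbinom(150, 1, 0.5))
  p <- withr::with_seed(6, runif(150))
  a1 <- dtiscreen:::roc_auc(y, p)
  expect_equal(dtiscreen:::roc_auc(y, plogis(5 * p - 2)), a1)
  expect_equal(dtiscreen:::roc_auc(y, p^3), a1)
})

test_that("training and evaluation are deterministic under a fixed seed", {
  ds <- tiny_signal_dataset()
  m1 <- train_forest(ds, n_trees = 40, max_features = 50, seed = 9)
  m2 <- train_forest(ds, n_trees = 40, max_features = 50, seed = 9)
  expect_identical(predict_probability(m1, ds$features),
                   predict_probability(m2, ds$features))
  cv1 <- cross_validate(ds, n_trees = 30, max_features = 50, folds = 3, seed = 11)
  cv2 <- cross_validate(ds, n_trees = 30, max_features = 50, folds = 3, seed = 11)
  expect_identical(cv1$fold_aucs, cv2$fold_aucs)
})

test_that("probabilities are leaf fractions: an overfit single tree is 0/1", {
  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 1, max_features = 200, seed = 3)
  p <- predict_probability(model, ds$features)
  expect_true(all(p %in% c(0, 1))) # fully grown leaves are pure
  # in-bag instances land in their own leaves; out-of-bag ones may not
  expect_gte(mean(p == ds$labels), 0.85)
})

test_that("class probabilities sum to one", {
  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 20, max_features = 50, seed = 3)
  raw <- predict(model$forest, data = ds$features, num.threads = 1)$predictions
  expect_true(all(abs(rowSums(raw) - 1) < 1e-12))
})

test_that("feature width and manifest mismatches are hard errors", {
  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 5, max_features = 20, seed = 1)
  expect_error(predict_probability(model, ds$features[, 1:700]),
               "755.*700|700.*755")
  bad <- ds$features
  colnames(bad) <- rev(colnames(bad))
  expect_error(predict_probability(model, bad), "manifest")
})

test_that("cross-validation separates signal from label noise", {
  cv_hi <- cross_validate(tiny_signal_dataset(), n_trees = 60,
                          max_features = 100, folds = 3, seed = 21)
  expect_gte(cv_hi$mean_auc, 0.9)
  cv_null <- cross_validate(tiny_null_dataset(), n_trees = 60,
                            max_features = 100, folds = 3, seed = 21)
  expect_lt(abs(cv_null$mean_auc - 0.5), 0.15)
})

test_that("stratification errors when a class cannot fill every fold", {
  ds <- tiny_signal_dataset()
  one_class <- dtiscreen:::subset_dataset(ds, ds$labels == 1)
  expect_error(cross_validate(one_class, folds = 3, seed = 1))
  expect_error(grid_search(one_class, tibble::tibble(n_trees = 5, max_features = 5)),
               "both classes")
})

test_that("grid search ties break toward fewer trees then smaller mtry", {
  # a trivially separable dataset drives every configuration to the same
  # accuracy, so the tie rule decides
  ds <- tiny_signal_dataset()
  sep <- ds
  # every feature separates the classes perfectly, so accuracy is 1 everywhere
  sep$features <- matrix(rep(ds$labels * 10, 8), ncol = 8,
                         dimnames = list(NULL, paste0("s", 1:8)))
  grid <- tibble::tibble(n_trees = c(150L, 100L), max_features = c(3L, 3L))
  gs <- grid_search(sep, grid, folds = 3, seed = 2)
  expect_equal(gs$n_trees, 100)
  grid2 <- tibble::tibble(n_trees = c(100L, 100L), max_features = c(5L, 3L))
  gs2 <- grid_search(sep, grid2, folds = 3, seed = 2)
  expect_equal(gs2$max_features, 3)
  gs3 <- grid_search(sep, grid2[2, ], folds = 3, seed = 2)
  expect_equal(gs3$max_features, 3)
})

test_that("permutation importance concentrates in the composition features carrying the signal", {
  # the generator injects signal through amino-acid composition; the paac
  # letter frequencies and CTD composition values are deterministic
  # functions of the same composition, so the recoverable signal lives in
  # that family. Many distinct proteins keep protein-identity memorization
  # from standing in for the feature signal.
  ds <- memo("perm_ds", function() {
    synthetic_dti_dataset(150, 150, effect_size = 8, seed = 77, n_proteins = 600)
  })
  model <- train_forest(ds, n_trees = 150, max_features = 100, seed = 5,
                        importance = "permutation")
  imp <- tidy(model)
  imp$importance <- pmax(imp$importance, 0)
  fam <- grepl("^aac_|^paac_[A-Z]$|^ctd_.*_C[123]$", imp$feature)
  expect_gte(sum(imp$importance[fam]) / sum(imp$importance), 0.5)
})

test_that("tidy and glance return well-formed summaries", {
  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 10, max_features = 30, seed = 2)
  td <- tidy(model)
  expect_equal(names(td), c("feature", "importance"))
  expect_equal(nrow(td), 755)
  gl <- glance(model)
  expect_equal(gl$n_trees, 10)
  ev <- evaluate(model, ds)
  gev <- glance(ev)
  expect_equal(gev$n, length(ds$labels))
  expect_true(gev$auc >= 0 && gev$auc <= 1)
})

test_that("model artifacts round-trip and manifest mismatches refuse to load", {
  ds <- tiny_signal_dataset()
  model <- train_forest(ds, n_trees = 5, max_features = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path, manifest = model$feature_names)
  expect_identical(back$feature_names, model$feature_names)
  expect_error(load_model(path, manifest = rev(model$feature_names)), "manifest")
})
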