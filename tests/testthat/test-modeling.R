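test_that("stratified split honours class-size rules and forms a partition", {
  labels <- c(rep("A", 10), rep("B", 4), rep("C", 2), rep("D", 20))
  df <- data.frame(id = sprintf("m%02d", seq_along(labels)), moa_label = labels,
                   smiles_raw = "C", stringsAsFactors = FALSE)
  sp <- stratified_split(df, "moa_label", split_spec(seed = 9))
  all_ids <- c(sp$train_ids, sp$test_ids, sp$excluded_ids)
  expect_setequal(all_ids, df$id)                     # partition
  expect_equal(length(all_ids), length(unique(all_ids)))  # disjoint
  counts <- function(ids, cls) sum(labels[match(ids, df$id)] == cls)
  expect_equal(counts(sp$train_ids, "A"), 8)  # class of 10 -> 8:2
  expect_equal(counts(sp$test_ids, "A"), 2)
  expect_equal(counts(sp$train_ids, "B"), 2)  # class of 4 -> 2:2
  expect_equal(counts(sp$test_ids, "B"), 2)
  expect_equal(counts(sp$train_ids, "D"), 16) # class of 20 -> 16:4
  # class of 2 excluded and relabelled Z
  expect_setequal(sp$excluded_ids, df$id[labels == "C"])
  expect_true(all(sp$labels[sp$excluded_ids] == "Z"))
  # deterministic given the seed
  sp2 <- stratified_split(df, "moa_label", split_spec(seed = 9))
  expect_identical(sp, sp2)
  expect_error(stratified_split(df, "nope"),
               class = "herbiscreen_validation_error")
})

test_that("confusion metrics reproduce the printed-formula worked example", {
  # TP=40, FN=10, FP=5, TN=45
  y_true <- c(rep("pos", 50), rep("neg", 50))
  y_pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 5), rep("neg", 45))
  m <- confusion_metrics(y_true, y_pred, "pos")
  expect_equal(m$TP, 40); expect_equal(m$FN, 10)
  expect_equal(m$FP, 5);  expect_equal(m$TN, 45)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 40 / 45)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (0.8 * 40 / 45) / (0.8 + 40 / 45))
  expect_equal(m$kappa, 0.7)
  expect_equal(m$balanced_accuracy, 0.85)
})

test_that("confusion metrics agree with the caret reference on random data", {
  skip_if_not_installed("caret")
  set.seed(8)
  y <- factor(sample(c("a", "b"), 80, TRUE))
  p <- factor(sample(c("a", "b"), 80, TRUE), levels = levels(y))
  cm <- caret::confusionMatrix(p, y, positive = "a")
  m <- confusion_metrics(as.character(y), as.character(p), "a")
  expect_equal(m$sensitivity, unname(cm$byClass["Sensitivity"]))
  expect_equal(m$specificity, unname(cm$byClass["Specificity"]))
  expect_equal(m$accuracy, unname(cm$overall["Accuracy"]))
  expect_equal(m$kappa, unname(cm$overall["Kappa"]))
})

test_that("degenerate predictors: constant output on balanced data gives kappa 0", {
  y_true <- rep(c("a", "b"), each = 50)
  y_pred <- rep("a", 100)
  m <- confusion_metrics(y_true, y_pred, "a")
  expect_equal(m$kappa, 0)
  # perfect prediction: everything 1
  p <- confusion_metrics(y_true, y_true, "a")
  expect_equal(p$sensitivity, 1); expect_equal(p$kappa, 1)
  expect_error(confusion_metrics(character(), character(), "a"),
               class = "herbiscreen_validation_error")
})

test_that("multi-class report matches a hand-computed confusion table", {
  # 3 classes, one systematic confusion: 5 of 15 B predicted as C
  y_true <- c(rep("A", 10), rep("B", 15), rep("C", 5))
  y_pred <- c(rep("A", 10), rep("B", 10), rep("C", 5), rep("C", 5))
  r <- multiclass_report(y_true, y_pred)
  expect_equal(r$overall_accuracy, 25 / 30)
  # per-class one-vs-rest, hand-derived: B: TP=10 FN=5 FP=0 TN=15
  b <- r$per_class[r$per_class$class == "B", ]
  expect_equal(b$sensitivity, 10 / 15)
  expect_equal(b$specificity, 1)
  # C: TP=5 FN=0 FP=5 TN=20
  cc <- r$per_class[r$per_class$class == "C", ]
  expect_equal(cc$precision, 0.5)
  # macro average is the unweighted mean of per-class values
  expect_equal(unname(r$macro["sensitivity"]),
               mean(r$per_class$sensitivity))
  # multi-class kappa: Po = 25/30, Pe from marginals
  pe <- (10 * 10 + 15 * 10 + 5 * 10) / 900
  expect_equal(r$kappa, (25 / 30 - pe) / (1 - pe))
  # perfect prediction
  perfect <- multiclass_report(y_true, y_true)
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(unname(perfect$macro["sensitivity"]), 1)
})

test_that("tuning is deterministic and honours a singleton grid", {
  cs <- scaffold_set()
  fp <- maccs_fingerprint(cs$smiles_clean, ids = cs$id)
  x <- unclass(apply_key_selection(fp, select_frequent_keys(fp, 2)))
  y <- cs$moa_label
  b1 <- tune_and_train(x, y, "rf", folds = 4, repeats = 1, seed = 17)
  b2 <- tune_and_train(x, y, "rf", folds = 4, repeats = 1, seed = 17)
  expect_identical(b1$best_params, b2$best_params)
  expect_identical(b1$cv_results$mean_accuracy, b2$cv_results$mean_accuracy)

  g <- data.frame(mtry = 3)
  b3 <- tune_and_train(x, y, "rf", grid = g, folds = 4, repeats = 1, seed = 1)
  expect_equal(b3$best_params$mtry, 3)
  expect_equal(nrow(b3$cv_results), 1)
  expect_true(all(!is.na(b3$resamples$accuracy)))

  expect_error(tune_and_train(x, rep("A", nrow(x)), "rf"),
               class = "herbiscreen_validation_error")
})

test_that("class probabilities are normalized and vote-based for random forests", {
  b <- moa_bundle()
  pr <- class_probabilities(b, b$x_train)
  expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(pr$prob)),
               tolerance = 1e-9)
  expect_true(all(pr$max_prob >= 1 / length(b$levels)))
  # RF probabilities are tree-vote fractions: ntree * p is an integer count
  ntree <- b$model$ntree
  raw <- stats::predict(b$model, newdata = b$x_train, type = "prob")
  expect_equal(raw * ntree, round(raw * ntree), tolerance = 1e-6,
               ignore_attr = TRUE)
  # on its own training set a well-fit model is confident and correct
  expect_true(all(pr$label == as.character(b$y_train)))
  expect_true(all(pr$max_prob > 0.6))
  expect_error(class_probabilities(b, b$x_train[, 1:3]),
               class = "herbiscreen_validation_error")
})

test_that("svm, nb and xgb adapters produce usable probability matrices", {
  ss <- selectivity_set()
  d <- physchem_profile(ss$smiles_clean, ids = ss$id)
  x <- scale_columns(as.matrix(d[, selectivity_descriptors()]))$scaled
  y <- ss$selectivity_label
  grids <- list(svm = NULL, nb = NULL,
                xgb = data.frame(max_depth = 3, eta = 0.3, nrounds = 30))
  for (alg in names(grids)) {
    if (alg == "xgb") skip_if_not_installed("xgboost")
    b <- tune_and_train(x, y, alg, grid = grids[[alg]], folds = 3,
                        repeats = 1, seed = 2)
    pr <- class_probabilities(b, x)
    expect_equal(dim(pr$prob), c(nrow(x), 3))
    expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(x)), tolerance = 1e-9)
    expect_gt(mean(pr$label == y), 0.5)  # far above chance on training data
  }
})
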