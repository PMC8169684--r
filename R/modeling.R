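# Stratified splitting, classifier tuning/training, performance metrics.

#' Splitting specification
#'
#' Defaults encode the study protocol: classes with fewer than
#' `min_class_size` (3) members are excluded from modelling and relabelled
#' "Z"; classes with 3-5 members are split 50:50; all larger classes 80:20
#' (train fraction rounded half-up, always leaving at least one test member).
#'
#' @param ratio_default Train fraction for ordinary classes.
#' @param ratio_small Train fraction for classes of 3-5 members.
#' @param small_range Inclusive size range treated as "small".
#' @param min_class_size Minimum members for a class to be modelled.
#' @param seed Integer seed making the split deterministic.
#' @return `split_spec` object.
#' @export
split_spec <- function(ratio_default = 0.8, ratio_small = 0.5,
                       small_range = c(3, 5), min_class_size = 3, seed = 1) {
  stopifnot(ratio_default > 0, ratio_default < 1,
            ratio_small > 0, ratio_small < 1, min_class_size >= 1)
  structure(list(ratio_default = ratio_default, ratio_small = ratio_small,
                 small_range = small_range, min_class_size = min_class_size,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split with small-class handling
#'
#' @param set A `compound_set` (or data frame with an `id` column).
#' @param label_field Name of the label column to stratify on.
#' @param spec A [split_spec()].
#' @return List: `train_ids`, `test_ids`, `excluded_ids` (classes below
#'   `min_class_size`, conceptually moved to the "Z" class), and
#'   `labels` (named vector of possibly relabelled values for all ids).
#' @export
stratified_split <- function(set, label_field = "moa_label",
                             spec = split_spec()) {
  df <- as.data.frame(set)
  if (!(label_field %in% names(df))) {
    validation_error(sprintf("label field '%s' absent", label_field))
  }
  lab <- as.character(df[[label_field]])
  if (anyNA(lab)) validation_error("every record must be labelled for splitting")
  ids <- df$id
  sizes <- table(lab)
  excluded <- ids[lab %in% names(sizes)[sizes < spec$min_class_size]]
  newlab <- stats::setNames(lab, ids)
  newlab[excluded] <- "Z"

  train <- character(); test <- character()
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  for (cls in sort(names(sizes)[sizes >= spec$min_class_size])) {
    members <- ids[lab == cls]
    n <- length(members)
    frac <- if (n >= spec$small_range[1] && n <= spec$small_range[2]) {
      spec$ratio_small
    } else {
      spec$ratio_default
    }
    n_train <- floor(frac * n + 0.5)
    n_train <- min(max(n_train, 1L), n - 1L)  # at least 1 in each part
    sel <- sample(members, n_train)
    train <- c(train, sel)
    test <- c(test, setdiff(members, sel))
  }
  list(train_ids = train, test_ids = test, excluded_ids = excluded,
       labels = newlab)
}

# Save/restore the RNG state so seeded operations do not disturb callers.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# ---- classifier adapters ----------------------------------------------------
# Each adapter exposes fit(x, y, params) -> model and prob(model, x) -> matrix
# of class probabilities with colnames = levels(y). The fitters themselves are
# the established implementations (randomForest, e1071, xgboost).

classifier_adapter <- function(algorithm) {
  switch(algorithm,
    rf = list(
      fit = function(x, y, p) {
        randomForest::randomForest(
          x = x, y = y,
          mtry = min(max(1L, as.integer(p$mtry)), ncol(x)),
          ntree = p$ntree %||% 500L)
      },
      prob = function(m, x) {
        pr <- stats::predict(m, newdata = x, type = "prob")
        matrix_or_row(pr)
      },
      default_grid = function(x, y) {
        p <- ncol(x)
        mtry <- sort(unique(pmax(1L, round(c(sqrt(p) / 2, sqrt(p),
                                             2 * sqrt(p), p / 3)))))
        data.frame(mtry = mtry)
      },
      complexity = function(g) g$mtry
    ),
    svm = list(
      fit = function(x, y, p) {
        e1071::svm(x = x, y = y, kernel = "radial",
                   cost = p$cost %||% 1, gamma = p$gamma %||% (1 / ncol(x)),
                   probability = TRUE, scale = FALSE)
      },
      prob = function(m, x) {
        pr <- attr(stats::predict(m, newdata = x, probability = TRUE),
                   "probabilities")
        matrix_or_row(pr)
      },
      default_grid = function(x, y) {
        expand.grid(cost = c(0.5, 1, 4, 16), gamma = (1 / ncol(x)) * c(0.5, 1, 2))
      },
      complexity = function(g) g$cost * 10 + g$gamma
    ),
    nb = list(
      fit = function(x, y, p) {
        e1071::naiveBayes(x = as.data.frame(x), y = y,
                          laplace = p$laplace %||% 0)
      },
      prob = function(m, x) {
        pr <- stats::predict(m, newdata = as.data.frame(x), type = "raw")
        matrix_or_row(pr)
      },
      default_grid = function(x, y) data.frame(laplace = c(0, 0.5, 1)),
      complexity = function(g) g$laplace
    ),
    xgb = list(
      fit = function(x, y, p) {
        if (!requireNamespace("xgboost", quietly = TRUE)) {
          config_error("xgboost not available")
        }
        nc <- nlevels(y)
        dm <- xgboost::xgb.DMatrix(as.matrix(x), label = as.integer(y) - 1L)
        m <- xgboost::xgb.train(
          params = list(objective = "multi:softprob", num_class = nc,
                        max_depth = p$max_depth %||% 4,
                        eta = p$eta %||% 0.3, nthread = 1),
          data = dm, nrounds = p$nrounds %||% 50, verbose = 0)
        attr(m, "levels") <- levels(y)
        m
      },
      prob = function(m, x) {
        lev <- attr(m, "levels")
        pr <- stats::predict(m, newdata = xgboost::xgb.DMatrix(as.matrix(x)))
        if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(lev), byrow = TRUE)
        colnames(pr) <- lev
        pr
      },
      default_grid = function(x, y) {
        expand.grid(max_depth = c(2, 4), eta = c(0.1, 0.3), nrounds = 50)
      },
      complexity = function(g) g$max_depth * 100 + g$nrounds
    ),
    config_error(sprintf("unknown algorithm '%s'", algorithm))
  )
}

matrix_or_row <- function(pr) {
  if (is.null(dim(pr))) matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
  else as.matrix(pr)
}

# Stratified fold assignment: members of each class are dealt round-robin
# over a shuffled fold order, so no fold ever holds out an entire class.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(sample(folds), length(idx))
  }
  assign
}

#' Grid-search tuning with repeated stratified cross-validation
#'
#' Hyperparameters are chosen by mean resampled accuracy over
#' `repeats` runs of `folds`-fold stratified CV; ties go to the least complex
#' grid point. The final model is refit on the full training set with the
#' selected parameters. All resample scores are retained.
#'
#' @param x Feature matrix (fingerprint bits or scaled descriptors).
#' @param y Class labels (coerced to factor; >= 2 classes, each with >= 2
#'   members).
#' @param algorithm One of "rf" (default), "svm", "nb", "xgb".
#' @param grid Data frame of hyperparameter combinations; NULL for the
#'   algorithm's default grid.
#' @param folds,repeats Cross-validation geometry (default 10 x 10).
#' @param seed Integer seed; the same seed, grid and data give identical
#'   selected hyperparameters.
#' @return A `classifier_bundle`: fitted model, `algorithm`, `best_params`,
#'   `cv_results` (per grid point mean/sd accuracy), `resamples` (every
#'   fold-level accuracy), `levels`, `features`, `x_train`, `y_train`.
#' @export
tune_and_train <- function(x, y, algorithm = "rf", grid = NULL,
                           folds = 10, repeats = 10, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) validation_error("need at least 2 classes")
  if (any(table(y) < 2)) validation_error("every class needs >= 2 members")
  if (nrow(x) != length(y)) validation_error("x/y length mismatch")
  ad <- classifier_adapter(algorithm)
  if (is.null(grid)) grid <- ad$default_grid(x, y)
  grid <- as.data.frame(grid)

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  resamples <- expand.grid(grid_row = seq_len(nrow(grid)),
                           repeat_ = seq_len(repeats),
                           fold = seq_len(folds))
  resamples$accuracy <- NA_real_
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      if (!any(hold) || all(hold)) next
      for (g in seq_len(nrow(grid))) {
        model <- ad$fit(x[!hold, , drop = FALSE], droplevels(y[!hold]),
                        as.list(grid[g, , drop = FALSE]))
        pr <- ad$prob(model, x[hold, , drop = FALSE])
        pred <- colnames(pr)[max.col(pr, ties.method = "first")]
        acc <- mean(pred == as.character(y[hold]))
        resamples$accuracy[resamples$grid_row == g &
                           resamples$repeat_ == r &
                           resamples$fold == f] <- acc
      }
    }
  }
  cv <- stats::aggregate(accuracy ~ grid_row, data = resamples,
                         FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  cv_mean <- cv$accuracy[, "mean"]
  best_acc <- max(cv_mean)
  cand <- cv$grid_row[cv_mean >= best_acc - 1e-12]
  comp <- ad$complexity(grid[cand, , drop = FALSE])
  best <- cand[order(comp)][1]

  final <- ad$fit(x, y, as.list(grid[best, , drop = FALSE]))
  structure(list(
    algorithm = algorithm, model = final,
    best_params = as.list(grid[best, , drop = FALSE]),
    grid = grid,
    cv_results = data.frame(grid[cv$grid_row, , drop = FALSE],
                            mean_accuracy = cv_mean,
                            sd_accuracy = cv$accuracy[, "sd"]),
    resamples = resamples,
    levels = levels(y), features = colnames(x),
    x_train = x, y_train = y, seed = as.integer(seed),
    cv_accuracy = best_acc
  ), class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %s | %d classes | %d features | CV acc %.3f\n",
              x$algorithm, length(x$levels), length(x$features), x$cv_accuracy))
  cat("best params:", paste(names(x$best_params), unlist(x$best_params),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Class probabilities, maxima and predicted labels
#'
#' For random forests the class probability is the fraction of trees voting
#' for the class; other algorithms return their native probability outputs.
#' Rows are renormalized to sum exactly to 1; argmax ties break in label
#' vocabulary order.
#'
#' @param bundle A `classifier_bundle`.
#' @param x Feature matrix with the bundle's training columns.
#' @return List: `prob` (n x n_classes matrix), `max_prob`, `label`.
#' @export
class_probabilities <- function(bundle, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!identical(colnames(x), bundle$features)) {
    if (!all(bundle$features %in% colnames(x))) {
      validation_error("feature columns do not match training features")
    }
    x <- x[, bundle$features, drop = FALSE]
  }
  ad <- classifier_adapter(bundle$algorithm)
  pr <- ad$prob(bundle$model, x)
  pr <- pr[, bundle$levels, drop = FALSE]
  pr <- pr / rowSums(pr)
  pred <- bundle$levels[max.col(pr, ties.method = "first")]
  list(prob = pr, max_prob = apply(pr, 1, max), label = pred)
}

#' One-vs-rest confusion metrics for a single class
#'
#' Computes TP/TN/FP/FN and the printed formulas: sensitivity (recall),
#' specificity, precision, accuracy, F1 and Cohen's kappa
#' ((Po - Pe) / (1 - Pe)); balanced accuracy is the mean of sensitivity and
#' specificity. A zero denominator yields a rate of 0 and sets the
#' `degenerate` flag.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive_class The class treated as positive.
#' @return One-row data frame of counts and rates.
#' @export
confusion_metrics <- function(y_true, y_pred, positive_class) {
  if (length(y_true) == 0) validation_error("empty inputs")
  if (length(y_true) != length(y_pred)) validation_error("length mismatch")
  t_pos <- y_true == positive_class
  p_pos <- y_pred == positive_class
  tp <- sum(t_pos & p_pos); fn <- sum(t_pos & !p_pos)
  fp <- sum(!t_pos & p_pos); tn <- sum(!t_pos & !p_pos)
  degenerate <- FALSE
  rate <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  n <- tp + tn + fp + fn
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  prec <- rate(tp, tp + fp)
  acc <- rate(tp + tn, n)
  f1 <- rate(2 * sens * prec, sens + prec)
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe == 1) { degenerate <- TRUE; 0 } else (po - pe) / (1 - pe)
  data.frame(class = positive_class, TP = tp, TN = tn, FP = fp, FN = fn,
             sensitivity = sens, specificity = spec, precision = prec,
             accuracy = acc, f1 = f1, balanced_accuracy = (sens + spec) / 2,
             kappa = kappa, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Multi-class performance report
#'
#' Per-class one-vs-rest metrics plus their unweighted macro averages, overall
#' accuracy, and the multi-class Cohen's kappa (Po - Pe)/(1 - Pe) with Pe from
#' the marginal products.
#'
#' @param y_true,y_pred Label vectors.
#' @param levels Optional label vocabulary (default: union of observed).
#' @return List: `per_class` data frame, `macro` named vector,
#'   `overall_accuracy`, `kappa`.
#' @export
multiclass_report <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) == 0) validation_error("empty inputs")
  if (length(y_true) != length(y_pred)) validation_error("length mismatch")
  if (is.null(levels)) levels <- sort(union(unique(y_true), unique(y_pred)))
  per <- do.call(rbind, lapply(levels, function(cl) {
    confusion_metrics(y_true, y_pred, cl)
  }))
  macro_cols <- c("sensitivity", "specificity", "precision", "f1",
                  "balanced_accuracy")
  macro <- colMeans(per[, macro_cols])
  n <- length(y_true)
  conf <- table(factor(y_true, levels = levels),
                factor(y_pred, levels = levels))
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(per_class = per, macro = macro, overall_accuracy = po, kappa = kappa)
}
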