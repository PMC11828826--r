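#' Train/test split specification
#'
#' @param train_frac Fraction of rows (or trials) in the training split
#'   (default 0.8).
#' @param stratified Preserve class proportions (default `TRUE`).
#' @param seed Seed for the split.
#' @param grouping `"none"` splits at window level (mirroring the study
#'   design; overlapping windows of one trial may then land on both sides) or
#'   `"by_trial"` keeps all windows of a trial on one side.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.8, stratified = TRUE, seed = 1,
                       grouping = c("none", "by_trial")) {
  grouping <- match.arg(grouping)
  stopifnot(train_frac > 0, train_frac < 1)
  structure(list(train_frac = train_frac, stratified = stratified,
                 seed = as.integer(seed), grouping = grouping),
            class = "split_spec")
}

#' Cross-validation specification
#'
#' @param n_folds Number of folds (default 6).
#' @param shuffled Shuffle before fold assignment (default `TRUE`).
#' @param seed Seed for fold assignment.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 6, shuffled = TRUE, seed = 1) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), shuffled = shuffled,
                 seed = as.integer(seed)),
            class = "cv_spec")
}

#' Classifier specification
#'
#' Four classical classifiers with exposed hyperparameters:
#' \describe{
#'   \item{knn}{k-nearest neighbours, Euclidean distance, `k = 5`; ties are
#'     broken by the class of the single nearest neighbour among the tied
#'     classes.}
#'   \item{svm}{RBF support vector machine, `cost = 1`,
#'     `gamma = 1 / (n_features * var(X))` (variance over all entries).}
#'   \item{dt}{CART decision tree, Gini impurity, unpruned (`cp = 0`,
#'     `minsplit = 2`).}
#'   \item{rf}{Random forest, 100 trees, `mtry = floor(sqrt(n_features))`
#'     (5 for the 25 band-power features).}
#' }
#'
#' @param kind One of `"knn"`, `"svm"`, `"dt"`, `"rf"`.
#' @param ... Hyperparameter overrides (`k`, `cost`, `gamma`, `cp`,
#'   `minsplit`, `ntree`, `mtry`).
#' @param seed Seed for stochastic fits.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("rf", "knn", "svm", "dt"), ..., seed = 1) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 5),
    svm = list(cost = 1, gamma = NULL),
    dt  = list(cp = 0, minsplit = 2),
    rf  = list(ntree = 100, mtry = NULL))
  hp <- modifyList(defaults, list(...))
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown)) stop("unknown hyperparameters for ", kind, ": ",
                            paste(unknown, collapse = ", "))
  structure(list(kind = kind, hyper = hp, seed = as.integer(seed)),
            class = "model_spec")
}

feature_columns <- function(features) {
  grep("^IMF[0-9]+_", names(features), value = TRUE)
}

#' Stratified train/test split of a feature table
#'
#' @param features Feature data frame from [extract_features()] (any data
#'   frame with a `label` column and, for `grouping = "by_trial"`, a `trial`
#'   column).
#' @param spec A [split_spec()].
#' @return List with data frames `train` and `test`.
#' @export
split_data <- function(features, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), "label" %in% names(features))
  y <- as.character(features$label)
  if (length(unique(y)) < 2) stop("need at least two classes to split")
  if (min(table(y)) < 2) stop("need at least two rows per class")
  idx_train <- withr::with_seed(spec$seed, {
    if (spec$grouping == "by_trial") {
      if (!"trial" %in% names(features)) stop("grouping by trial needs a trial column")
      tr_lab <- tapply(y, features$trial, function(v) v[1])
      trials <- as.numeric(names(tr_lab))
      picked <- unlist(lapply(split(trials, tr_lab), function(tt) {
        n_tr <- max(1, round(length(tt) * spec$train_frac))
        sample(tt, n_tr)
      }), use.names = FALSE)
      which(features$trial %in% picked)
    } else if (spec$stratified) {
      unlist(lapply(split(seq_along(y), y), function(ii) {
        sample(ii, round(length(ii) * spec$train_frac))
      }), use.names = FALSE)
    } else {
      sample(seq_along(y), round(length(y) * spec$train_frac))
    }
  })
  train <- features[sort(idx_train), , drop = FALSE]
  test <- features[-sort(idx_train), , drop = FALSE]
  if (length(setdiff(unique(y), unique(train$label))) > 0 ||
      length(setdiff(unique(y), unique(test$label))) > 0)
    stop("a class is absent from one side of the split")
  list(train = train, test = test)
}

fit_model <- function(train, spec, feature_cols = NULL) {
  cols <- feature_cols %||% feature_columns(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  y <- factor(as.character(train$label))
  fit <- withr::with_seed(spec$seed, switch(spec$kind,
    knn = list(x = x, y = y, k = spec$hyper$k),
    svm = {
      gamma <- spec$hyper$gamma %||% (1 / (ncol(x) * max(var(as.vector(x)), 1e-12)))
      e1071::svm(x, y, kernel = "radial", cost = spec$hyper$cost,
                 gamma = gamma, scale = FALSE)
    },
    dt = {
      df <- data.frame(x, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = spec$hyper$cp,
                                                  minsplit = spec$hyper$minsplit,
                                                  xval = 0))
    },
    rf = {
      mtry <- spec$hyper$mtry %||% max(1, floor(sqrt(ncol(x))))
      randomForest::randomForest(x, y, ntree = spec$hyper$ntree, mtry = mtry,
                                 importance = TRUE)
    }))
  structure(list(kind = spec$kind, fit = fit, levels = levels(y), cols = cols),
            class = "vmdeeg_fit")
}

predict_model <- function(model, newdata) {
  x <- as.matrix(newdata[, model$cols, drop = FALSE])
  out <- switch(model$kind,
    knn = knn_predict(model$fit$x, model$fit$y, x, model$fit$k),
    svm = as.character(predict(model$fit, x)),
    dt  = as.character(predict(model$fit,
                               data.frame(x, check.names = FALSE),
                               type = "class")),
    rf  = as.character(predict(model$fit, x)))
  factor(out, levels = model$levels)
}

# Euclidean KNN with deterministic tie-breaking: on a tied vote, the class of
# the nearest neighbour belonging to a tied class wins.
knn_predict <- function(xtr, ytr, xte, k) {
  ytr <- as.character(ytr)
  apply(xte, 1, function(p) {
    d <- sqrt(colSums((t(xtr) - p)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- table(ytr[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top
    else ytr[nn[ytr[nn] %in% top][1]]
  })
}

stratified_folds <- function(y, cv) {
  y <- as.character(y)
  if (min(table(y)) < cv$n_folds)
    stop("fold count exceeds the smallest class count")
  folds <- integer(length(y))
  withr::with_seed(cv$seed, {
    for (cls in unique(y)) {
      ii <- which(y == cls)
      if (cv$shuffled) ii <- sample(ii)
      folds[ii] <- rep_len(seq_len(cv$n_folds), length(ii))
    }
  })
  folds
}

cv_accuracy <- function(train, model, cv, feature_cols = NULL) {
  folds <- stratified_folds(train$label, cv)
  scores <- vapply(seq_len(cv$n_folds), function(f) {
    fit <- fit_model(train[folds != f, , drop = FALSE], model, feature_cols)
    pred <- predict_model(fit, train[folds == f, , drop = FALSE])
    mean(as.character(pred) == as.character(train$label[folds == f]))
  }, numeric(1))
  scores
}

#' Train a classifier and evaluate it
#'
#' Splits the feature table, estimates validation accuracy by stratified
#' k-fold cross-validation on the training split, refits on the full training
#' split, and reports held-out test metrics: accuracy, macro-averaged
#' precision/recall/F1, and the confusion matrix (rows = true class,
#' columns = predicted).
#'
#' @param features Feature data frame with a `label` column.
#' @param model A [model_spec()].
#' @param split A [split_spec()].
#' @param cv A [cv_spec()].
#' @return An object of class `eval_report`.
#' @export
train_eval <- function(features, model = model_spec("rf"),
                       split = split_spec(), cv = cv_spec()) {
  parts <- split_data(features, split)
  fold_scores <- cv_accuracy(parts$train, model, cv)
  fit <- fit_model(parts$train, model)
  pred <- predict_model(fit, parts$test)
  truth <- factor(as.character(parts$test$label), levels = fit$levels)
  cm <- table(truth = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    validation_accuracy = mean(fold_scores),
    fold_scores = fold_scores,
    test_accuracy = acc,
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    confusion = cm,
    n_train = nrow(parts$train), n_test = nrow(parts$test),
    model = model, split = split, cv = cv,
    fit = fit, test_rows = parts$test, train_rows = parts$train
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: validation accuracy %.4f (6-fold: %s)\n", x$model$kind,
              x$validation_accuracy,
              paste(sprintf("%.3f", x$fold_scores), collapse = " ")))
  cat(sprintf("  test accuracy %.4f | macro P %.4f R %.4f F1 %.4f (n=%d)\n",
              x$test_accuracy, x$precision, x$recall, x$f1, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' Window-length sweep
#'
#' Re-runs feature extraction and evaluation for every window length and every
#' classifier, mirroring the study's window-sweep design. A failing cell (for
#' instance a window longer than the recording) is recorded with its error
#' message without affecting the other cells.
#'
#' @param recordings One `eeg_recording` or a list of them.
#' @param lengths_s Window lengths in seconds (default `c(1, 2, 3, 4, 15)`).
#' @param models Character vector of classifier kinds, or a list of
#'   [model_spec()] objects.
#' @param overlap_frac Window overlap (default 0.5).
#' @param vmd,split,cv As elsewhere.
#' @return Tidy data frame: one row per (model, window length) with
#'   `validation_accuracy`, `test_accuracy`, `n_windows`, `error`.
#' @export
sweep_windows <- function(recordings, lengths_s = c(1, 2, 3, 4, 15),
                          models = c("knn", "svm", "dt", "rf"),
                          overlap_frac = 0.5, vmd = vmd_config(),
                          split = split_spec(), cv = cv_spec()) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (is.character(models))
    models <- lapply(models, function(k) model_spec(k))
  out <- list()
  for (len in lengths_s) {
    feats <- tryCatch(
      extract_features_multi(recordings, window_spec(len, overlap_frac), vmd),
      error = function(e) e)
    for (m in models) {
      row <- data.frame(model = m$kind, window_s = len,
                        validation_accuracy = NA_real_,
                        test_accuracy = NA_real_, n_windows = NA_integer_,
                        error = NA_character_, stringsAsFactors = FALSE)
      if (inherits(feats, "error")) {
        row$error <- conditionMessage(feats)
      } else {
        rep_ <- tryCatch(train_eval(feats, m, split, cv), error = function(e) e)
        if (inherits(rep_, "error")) {
          row$error <- conditionMessage(rep_)
          row$n_windows <- nrow(feats)
        } else {
          row$validation_accuracy <- rep_$validation_accuracy
          row$test_accuracy <- rep_$test_accuracy
          row$n_windows <- nrow(feats)
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Per-IMF / per-band ablation table
#'
#' Cross-validated validation accuracy (on the training split) for every
#' feature subset: each single (IMF, band) cell, each IMF row with all bands
#' combined, each band column with all IMFs combined, and all 25 features
#' together.
#'
#' @param features Full feature table (all `IMF{k}_{Band}` columns present).
#' @param model A [model_spec()] (the study uses the random forest here).
#' @param split,cv As elsewhere.
#' @return 6 x 6 numeric matrix; rows `IMF1..IMF5, All IMFs`, columns
#'   `Delta..Gamma, Combined`.
#' @export
ablation_table <- function(features, model = model_spec("rf"),
                           split = split_spec(), cv = cv_spec()) {
  bands <- eeg_bands()$band
  K <- length(grep("^IMF[0-9]+_Delta$", names(features)))
  if (K == 0) stop("features lack IMF{k}_{Band} columns")
  parts <- split_data(features, split)
  rows <- c(paste0("IMF", seq_len(K)), "All IMFs")
  cols <- c(bands, "Combined")
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    imfs <- if (i <= K) i else seq_len(K)
    bnds <- if (j <= length(bands)) bands[j] else bands
    subset_cols <- as.vector(outer(paste0("IMF", imfs),
                                   bnds, paste, sep = "_"))
    out[i, j] <- mean(cv_accuracy(parts$train, model, cv, subset_cols))
  }
  out
}
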