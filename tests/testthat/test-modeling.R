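test_that("stratified splitting preserves class counts and is seed-deterministic", {
  f <- make_blob_features(n_per_class = 30)
  parts <- split_data(f, split_spec(0.8, seed = 4))
  expect_identical(nrow(parts$train), 72L)
  expect_identical(nrow(parts$test), 18L)
  expect_true(all(table(parts$test$label) == 6))
  parts2 <- split_data(f, split_spec(0.8, seed = 4))
  expect_identical(parts$train, parts2$train)
  # single class cannot be split
  f1 <- f[f$label == "happy", ]
  expect_error(split_data(f1, split_spec()), "two classes")
})

test_that("trial grouping keeps all windows of a trial on one side", {
  f <- make_blob_features(n_per_class = 30)
  parts <- split_data(f, split_spec(0.8, seed = 2, grouping = "by_trial"))
  both <- intersect(unique(parts$train$trial), unique(parts$test$trial))
  expect_length(both, 0)
})

test_that("separable classes are classified perfectly; fold limits are enforced", {
  f <- make_blob_features(n_per_class = 30)
  for (kind in c("rf", "knn")) {
    r <- train_eval(f, model_spec(kind), split_spec(seed = 1), cv_spec(seed = 1))
    expect_identical(r$test_accuracy, 1)
    expect_gte(r$validation_accuracy, 0.99)
  }
  expect_error(train_eval(f, model_spec("rf"), split_spec(),
                          cv_spec(n_folds = 30)),
               "fold count")
})

test_that("all four classifiers produce consistent reports on the demo features", {
  f <- demo_features_pooled()
  for (kind in c("knn", "svm", "dt", "rf")) {
    r <- train_eval(f, model_spec(kind), split_spec(seed = 3), cv_spec(seed = 3))
    expect_true(all(c(r$validation_accuracy, r$test_accuracy, r$precision,
                      r$recall, r$f1) >= 0))
    expect_true(all(c(r$precision, r$recall, r$f1) <= 1))
    # confusion conservation: row sums are the true class counts
    expect_identical(sum(r$confusion), r$n_test)
    expect_equal(rowSums(r$confusion),
                 table(factor(as.character(r$test_rows$label),
                              levels = r$fit$levels)),
                 ignore_attr = TRUE)
    expect_equal(sum(diag(r$confusion)) / r$n_test, r$test_accuracy)
  }
})

test_that("reports are identical under fixed seeds", {
  f <- demo_features_pooled()
  a <- train_eval(f, model_spec("rf", seed = 5), split_spec(seed = 5),
                  cv_spec(seed = 5))
  b <- train_eval(f, model_spec("rf", seed = 5), split_spec(seed = 5),
                  cv_spec(seed = 5))
  expect_identical(a$fold_scores, b$fold_scores)
  expect_identical(a$confusion, b$confusion)
})

test_that("label-permuted features score at chance level", {
  f <- make_blob_features(n_per_class = 110, seed = 6)   # 330 rows
  preds <- 0L; total <- 0L
  for (rep_i in 1:20) {
    fp <- f
    fp$label <- withr::with_seed(100 + rep_i, sample(fp$label))
    r <- train_eval(fp, model_spec("rf", seed = rep_i),
                    split_spec(seed = rep_i), cv_spec(seed = rep_i))
    preds <- preds + sum(diag(r$confusion))
    total <- total + r$n_test
  }
  ci <- chance_ci(total)
  expect_gte(preds / total, ci[1])
  expect_lte(preds / total, ci[2])
})

test_that("the window sweep is consistent with a single evaluation and isolates failures", {
  s <- demo_session()
  sp <- split_spec(seed = 2); cvp <- cv_spec(seed = 2)
  tab <- sweep_windows(s$clean, lengths_s = c(3, 120), models = "rf",
                       split = sp, cv = cvp)
  expect_identical(nrow(tab), 2L)
  ref <- train_eval(extract_features(s$clean, window_spec(3, 0.5)),
                    model_spec("rf"), sp, cvp)
  ok <- tab[tab$window_s == 3, ]
  expect_equal(ok$validation_accuracy, ref$validation_accuracy)
  expect_equal(ok$test_accuracy, ref$test_accuracy)
  expect_true(is.na(ok$error))
  # the infeasible 120 s cell fails alone, with its error recorded
  bad <- tab[tab$window_s == 120, ]
  expect_true(is.na(bad$validation_accuracy))
  expect_match(bad$error, "longer")
})

test_that("the ablation grid recovers the planted (IMF, band) cell", {
  f <- demo_features_pooled()
  tab <- ablation_table(f, model_spec("rf", seed = 7), split_spec(seed = 7),
                        cv_spec(seed = 7))
  expect_identical(dim(tab), c(6L, 6L))
  expect_true(all(tab >= 0 & tab <= 1))
  single <- tab[1:5, 1:5]
  best <- which(single == max(single), arr.ind = TRUE)[1, ]
  expect_identical(rownames(single)[best["row"]], "IMF1")
  expect_identical(colnames(single)[best["col"]], "Delta")
  # pooling features never hurts much: the combined cell is near the maximum
  expect_gte(tab["All IMFs", "Combined"], max(single) - 0.05)
})

test_that("importance methods rank the planted feature first and agree", {
  f <- demo_features_pooled()
  r <- train_eval(f, model_spec("rf", seed = 8), split_spec(seed = 8),
                  cv_spec(seed = 8))
  tree_imp <- explain(r, method = "tree")
  perm_imp <- explain(r, method = "permutation", seed = 8)
  expect_identical(tree_imp$ranking[1], "IMF1_Delta")
  expect_identical(perm_imp$ranking[1], "IMF1_Delta")
  expect_identical(dim(tree_imp$attributions), c(25L, 3L))
  expect_identical(dim(perm_imp$attributions), c(25L, 3L))
  # constant features carry no attribution (model-agnostic path; the
  # randomForest C routine does not terminate on all-constant predictors)
  fc <- f
  fc[vmdeeg:::feature_names(5)] <- 1
  rc <- train_eval(fc, model_spec("knn"), split_spec(seed = 8),
                   cv_spec(seed = 8))
  expect_lte(max(abs(explain(rc, method = "permutation")$attributions)), 1e-9)
  # tree attribution requires a forest
  rk <- train_eval(f, model_spec("knn"), split_spec(seed = 8), cv_spec(seed = 8))
  expect_error(explain(rk, method = "tree"), "random-forest")
})
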