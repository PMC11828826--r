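#' Feature-importance report
#'
#' Per-feature, per-class mean absolute attribution for a trained classifier,
#' with a descending overall ranking. Two methods share one report schema:
#' \describe{
#'   \item{tree}{The random forest's out-of-bag per-class permutation
#'     importance (mean decrease in class accuracy when the feature is
#'     permuted within the ensemble); available for `rf` fits only.}
#'   \item{permutation}{Model-agnostic seeded permutation importance on the
#'     held-out test rows: for each feature, the mean absolute drop in
#'     per-class recall over `n_repeats` shuffles.}
#' }
#'
#' @param report An [train_eval()] `eval_report` (carries the fitted model and
#'   the split).
#' @param method `"tree"` or `"permutation"`.
#' @param n_repeats Shuffles per feature for the permutation method
#'   (default 20).
#' @param seed Seed for the permutation draws.
#' @return An object of class `importance_report`: `attributions` (features x
#'   classes matrix of mean absolute attributions), `overall` (named vector,
#'   mean over classes), `ranking` (feature names, descending), `method`.
#' @export
explain <- function(report, method = c("tree", "permutation"),
                    n_repeats = 20, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(report, "eval_report"))
  fit <- report$fit
  if (is.null(fit)) stop("report carries no fitted model")
  classes <- fit$levels
  cols <- fit$cols

  if (method == "tree") {
    if (fit$kind != "rf")
      stop("tree attribution needs a random-forest fit; use method = 'permutation'")
    att <- abs(fit$fit$importance[, classes, drop = FALSE])
  } else {
    test <- report$test_rows
    x <- test[, cols, drop = FALSE]
    truth <- as.character(test$label)
    base_pred <- as.character(predict_model(fit, test))
    base_recall <- vapply(classes, function(cl)
      mean(base_pred[truth == cl] == cl), numeric(1))
    att <- matrix(0, length(cols), length(classes),
                  dimnames = list(cols, classes))
    withr::with_seed(as.integer(seed), {
      for (j in seq_along(cols)) {
        drops <- matrix(0, n_repeats, length(classes))
        for (r in seq_len(n_repeats)) {
          perm <- test
          perm[[cols[j]]] <- sample(perm[[cols[j]]])
          pred <- as.character(predict_model(fit, perm))
          rec <- vapply(classes, function(cl)
            mean(pred[truth == cl] == cl), numeric(1))
          drops[r, ] <- abs(base_recall - rec)
        }
        att[j, ] <- colMeans(drops)
      }
    })
  }
  if (any(!is.finite(att))) stop("non-finite attributions")
  overall <- rowMeans(att)
  structure(list(attributions = att, overall = overall,
                 ranking = names(sort(overall, decreasing = TRUE)),
                 method = method),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, n = 6, ...) {
  cat("Feature importance (", x$method, "), top ", n, " of ",
      length(x$overall), ":\n", sep = "")
  top <- head(x$ranking, n)
  for (f in top)
    cat(sprintf("  %-12s %.5f  (%s)\n", f, x$overall[f],
                paste(sprintf("%s %.4f", colnames(x$attributions),
                              x$attributions[f, ]), collapse = ", ")))
  invisible(x)
}
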