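# Balanced one-vs-rest linear SVM, repeated stratified cross-validation,
# the four confusion-matrix metrics, and per-behavior confusion rates.

#' Undersample the majority class to balance a binary problem
#'
#' The minority class is kept whole; the majority class is randomly
#' undersampled without replacement down to the minority count, so the
#' classifier cannot lean on class priors.
#'
#' @param X feature matrix (rows = samples).
#' @param y 0/1 labels.
#' @param seed integer seed; the same seed always selects the same rows.
#' @return list with `X`, `y`, and `idx` (the retained row indices of the
#'   original matrix, in original order).
#' @export
balance_classes <- function(X, y, seed) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  tab <- table(y)
  minority <- as.integer(names(tab)[which.min(tab)])
  keep_min <- which(y == minority)
  maj <- which(y != minority)
  set.seed(seed)
  keep_maj <- sort(sample(maj, length(keep_min)))
  idx <- sort(c(keep_min, keep_maj))
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `f1 = 2*precision*recall/(precision+recall)`.
#' A zero denominator in precision, recall or F1 yields 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return named vector `(accuracy, precision, recall, f1)`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("no evaluated samples")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / n, precision = precision, recall = recall, f1 = f1)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' across folds, so every fold's class proportions match the whole within
#' one sample.
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(y, k, seed) {
  if (any(table(y) < k)) stop("each class needs at least as many samples as folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  fold
}

# Standardized linear SVM: z-scoring is fitted on the training portion
# only (a margin classifier across mixed-unit features needs it) and the
# frozen transform is applied at prediction time.
fit_linear_svm <- function(X, y, C, standardize = TRUE) {
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  fit <- e1071::svm(Xs, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_,
                 C = C, standardize = standardize),
            class = "mount_svm")
}

#' Predict with a fitted mount-detection SVM
#'
#' @param object a model from the pipeline's internal fitter.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return integer 0/1 predictions.
#' @export
predict.mount_svm <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  as.integer(as.character(predict(object$fit, Xs)))
}

# one train/test evaluation -> confusion counts
eval_split <- function(X, y, train, test, C, standardize = TRUE) {
  model <- fit_linear_svm(X[train, , drop = FALSE], y[train], C, standardize)
  pred <- predict(model, X[test, , drop = FALSE])
  truth <- y[test]
  c(tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Grid search for the SVM regularization parameter C
#'
#' Evaluates every candidate by stratified k-fold mean F1 (single repeat)
#' and returns the argmax; ties break toward the smallest C.
#'
#' @param X,y data (binary labels).
#' @param grid candidate C values (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment is shared across candidates,
#'   so the comparison is paired).
#' @param standardize z-score features on each training fold.
#' @return list with `best_C` and `scores` (named mean F1 per candidate).
#' @export
grid_search_C <- function(X, y, grid = c(0.01, 0.1, 1, 10, 100), folds = 5,
                          seed = 1, standardize = TRUE) {
  if (!length(grid)) stop("empty grid")
  grid <- sort(grid)
  fold <- stratified_folds(y, folds, seed)
  scores <- vapply(grid, function(C) {
    f1s <- vapply(seq_len(folds), function(k) {
      cc <- eval_split(X, y, which(fold != k), which(fold == k), C, standardize)
      compute_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])[["f1"]]
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  names(scores) <- as.character(grid)
  list(best_C = grid[which.max(scores)], scores = scores)
}

#' Repeated stratified k-fold cross-validation of the linear SVM
#'
#' The default 5-fold x 20-repeat scheme yields 100 train/test fits; each
#' records its confusion counts and the four metrics, giving a
#' distribution of scores rather than a single estimate.
#'
#' @param X,y data (binary labels; each class count must be >= `folds`).
#' @param folds folds per repeat (5).
#' @param repeats number of re-drawn fold assignments (20).
#' @param C SVM regularization parameter.
#' @param seed integer seed; fold assignments for repeat r derive from it.
#' @param standardize z-score features on each training fold.
#' @return object of class `cv_result`: list with `iterations`
#'   (data.frame: iteration, rep, fold, tp..fn, accuracy..f1), `C`,
#'   `seed`, `folds`, `repeats`.
#' @export
repeated_stratified_cv <- function(X, y, folds = 5, repeats = 20, C = 0.1,
                                   seed = 1, standardize = TRUE) {
  if (any(table(y) < folds)) stop("each class needs at least `folds` samples")
  rows <- vector("list", folds * repeats)
  it <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, derive_seed(seed, r))
    for (k in seq_len(folds)) {
      it <- it + 1L
      cc <- eval_split(X, y, which(fold != k), which(fold == k), C, standardize)
      met <- compute_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
      rows[[it]] <- data.frame(iteration = it, rep = r, fold = k,
                               tp = cc[["tp"]], tn = cc[["tn"]],
                               fp = cc[["fp"]], fn = cc[["fn"]],
                               accuracy = met[["accuracy"]],
                               precision = met[["precision"]],
                               recall = met[["recall"]], f1 = met[["f1"]])
    }
  }
  structure(list(iterations = do.call(rbind, rows), C = C, seed = seed,
                 folds = folds, repeats = repeats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- colMeans(x$iterations[c("accuracy", "precision", "recall", "f1")])
  cat(sprintf("<cv_result> %d x %d = %d iterations, C = %g\n",
              x$folds, x$repeats, nrow(x$iterations), x$C))
  cat(sprintf("  mean accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              m[1], m[2], m[3], m[4]))
  invisible(x)
}

#' Summarize a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with mean/median/sd for each metric.
#' @export
summary.cv_result <- function(object, ...) {
  mets <- object$iterations[c("accuracy", "precision", "recall", "f1")]
  data.frame(metric = names(mets),
             mean = vapply(mets, mean, numeric(1)),
             median = vapply(mets, median, numeric(1)),
             sd = vapply(mets, sd, numeric(1)),
             row.names = NULL)
}

#' Per-behavior false-positive (confusion) rate
#'
#' Applies a fitted binary mount detector to windows tagged with their
#' five-class behavior and reports, for each non-mount behavior, the count
#' and percentage misclassified as an active mount.
#'
#' @param model fitted model accepted by `predict` (rows of `X` -> 0/1).
#' @param X feature matrix.
#' @param behavior character vector of true five-class behaviors, one per
#'   row of `X`.
#' @return data.frame `(behavior, n, fp, rate_pct)`; behaviors with n = 0
#'   are omitted.
#' @export
confusion_by_behavior <- function(model, X, behavior) {
  stopifnot(nrow(X) == length(behavior))
  nonmount <- behavior != "active_mounting"
  pred <- predict(model, X[nonmount, , drop = FALSE])
  beh <- behavior[nonmount]
  out <- do.call(rbind, lapply(setdiff(behaviors, "active_mounting"), function(b) {
    n <- sum(beh == b)
    if (n == 0) return(NULL)
    fp <- sum(pred[beh == b] == 1)
    data.frame(behavior = b, n = n, fp = fp,
               rate_pct = confusion_rate_pct(n, fp))
  }))
  out
}

#' Confusion rate from counts
#'
#' @param n number of evaluated windows of a behavior.
#' @param fp how many were misclassified as active mounts.
#' @return `100 * fp / n`, in percent.
#' @export
confusion_rate_pct <- function(n, fp) {
  stopifnot(n > 0, fp >= 0, fp <= n)
  100 * fp / n
}

#' Export per-iteration CV metrics to CSV
#'
#' @param cv a `cv_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  write.csv(cv$iterations[c("iteration", "fold", "rep", "accuracy",
                            "precision", "recall", "f1")],
            path, row.names = FALSE)
  invisible(path)
}
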