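# Sequential backward selection (wrapper, CV-F1 driven) and permutation
# importance.

# default SBS evaluator: stratified k-fold (single repeat) mean F1 of the
# linear SVM; folds are fixed once per sbs() call so all candidate
# removals within and across steps are compared on identical splits
make_cv_f1_evaluator <- function(y, folds = 5, C = 0.1, seed = 1,
                                 standardize = TRUE) {
  fold <- stratified_folds(y, folds, seed)
  function(Xsub, ysub) {
    f1s <- vapply(seq_len(max(fold)), function(k) {
      cc <- eval_split(Xsub, ysub, which(fold != k), which(fold == k), C,
                       standardize)
      compute_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])[["f1"]]
    }, numeric(1))
    mean(f1s)
  }
}

#' Sequential Backward Selection
#'
#' Greedy wrapper elimination: starting from all features, each step
#' evaluates every single-feature removal with a cross-validated F1
#' evaluator and removes the feature whose removal leaves the highest F1
#' (ties break toward the earliest column, making runs reproducible).
#' Elimination continues down to `stop_size`; the best subset is the
#' argmax of F1 over all visited sizes (including the full set).
#'
#' @param X feature matrix with column names.
#' @param y 0/1 labels.
#' @param stop_size smallest subset size to visit (default 1, i.e. the
#'   full elimination path; pass 13 to reproduce a fixed-size selection).
#' @param evaluator `function(Xsub, y) -> F1`; default is stratified
#'   `folds`-fold single-repeat CV of the linear SVM at cost `C`.
#' @param folds,C,standardize parameters of the default evaluator.
#' @param seed integer seed (fixes the evaluator's fold assignment).
#' @return object of class `selection_trace`: list with `trace`
#'   (data.frame: step, removed, n_remaining, f1_after), `start_f1`,
#'   `best_subset` (character), `best_f1`.
#' @export
sbs <- function(X, y, stop_size = 1, evaluator = NULL, folds = 5, C = 0.1,
                standardize = TRUE, seed = 1) {
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  if (stop_size < 1 || stop_size >= p) {
    stop("stop_size must be in [1, ncol(X) - 1]")
  }
  if (is.null(evaluator)) {
    evaluator <- make_cv_f1_evaluator(y, folds = folds, C = C, seed = seed,
                                      standardize = standardize)
  }
  current <- seq_len(p)
  start_f1 <- evaluator(X[, current, drop = FALSE], y)
  best_subset <- current; best_f1 <- start_f1
  steps <- list()
  step <- 0L
  while (length(current) > stop_size) {
    step <- step + 1L
    f1_after <- vapply(seq_along(current), function(i) {
      evaluator(X[, current[-i], drop = FALSE], y)
    }, numeric(1))
    drop_i <- which.max(f1_after)   # first of ties = earliest column order
    steps[[step]] <- data.frame(step = step,
                                removed = colnames(X)[current[drop_i]],
                                n_remaining = length(current) - 1L,
                                f1_after = f1_after[drop_i])
    current <- current[-drop_i]
    if (f1_after[drop_i] > best_f1) {
      best_f1 <- f1_after[drop_i]
      best_subset <- current
    }
  }
  structure(list(trace = do.call(rbind, steps),
                 start_f1 = start_f1,
                 best_subset = colnames(X)[best_subset],
                 best_f1 = best_f1),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d removals; best F1 %.3f with %d features\n",
              nrow(x$trace), x$best_f1, length(x$best_subset)))
  invisible(x)
}

#' Permutation importance
#'
#' For each feature: the mean drop in F1 (over `repeats` seeded
#' permutations) when that column is shuffled while everything else stays
#' intact. Features the model ignores score ~0.
#'
#' @param model fitted model accepted by `predict` (0/1 output).
#' @param X,y evaluation data.
#' @param repeats permutations per feature.
#' @param seed integer seed.
#' @return data.frame `(feature, importance)` in column order;
#'   `importance` = baseline F1 minus mean permuted F1.
#' @export
permutation_importance <- function(model, X, y, repeats = 10, seed = 1) {
  stopifnot(repeats >= 1)
  f1_of <- function(pred) {
    compute_metrics(sum(pred == 1 & y == 1), sum(pred == 0 & y == 0),
                    sum(pred == 1 & y == 0), sum(pred == 0 & y == 1))[["f1"]]
  }
  baseline <- f1_of(predict(model, X))
  p <- ncol(X)
  imp <- numeric(p)
  for (j in seq_len(p)) {
    set.seed(derive_seed(seed, j))
    drops <- vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      baseline - f1_of(predict(model, Xp))
    }, numeric(1))
    imp[j] <- mean(drops)
  }
  data.frame(feature = colnames(X) %||% paste0("f", seq_len(p)),
             importance = imp)
}

#' Export an SBS trace to CSV
#'
#' @param trace a `selection_trace`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace$trace, path, row.names = FALSE)
  invisible(path)
}
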