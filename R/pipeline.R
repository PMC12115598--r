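# End-to-end experiment: database -> features -> balance -> grid-searched
# linear SVM under repeated stratified CV -> (optional) SBS -> body-vs-
# world statistical comparison. All randomness flows from one root seed
# through named substreams so the two frames see identical events,
# balancing and fold assignments (a paired comparison).

#' Experiment configuration
#'
#' @param db_root database directory (`NULL` when recordings are passed
#'   to [run_experiment()] directly).
#' @param frames which acceleration frames to run: `"body"`, `"world"`,
#'   or both (default both, enabling the paired comparison).
#' @param window_s analysis window, seconds.
#' @param window_mode `"first"` or `"tiled"`, see [segment_windows()].
#' @param c_grid candidate SVM costs for the grid search.
#' @param folds,repeats cross-validation scheme (5 x 20 = 100 fits).
#' @param seed root seed.
#' @param balance undersample the majority class before CV.
#' @param standardize z-score features inside each training fold.
#' @param sbs run sequential backward selection per frame.
#' @param sbs_stop_size smallest SBS subset size (`NULL` = down to 1).
#' @param alpha significance level for the frame comparison.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(db_root = NULL, frames = c("body", "world"),
                       window_s = 7, window_mode = "first",
                       c_grid = c(0.01, 0.1, 1, 10, 100),
                       folds = 5, repeats = 20, seed = 1, balance = TRUE,
                       standardize = TRUE, sbs = FALSE, sbs_stop_size = NULL,
                       alpha = 0.05) {
  frames <- match.arg(frames, c("body", "world"), several.ok = TRUE)
  stopifnot(folds >= 2, repeats >= 1, window_s > 0, length(c_grid) >= 1)
  structure(list(db_root = db_root, frames = frames, window_s = window_s,
                 window_mode = window_mode, c_grid = c_grid, folds = folds,
                 repeats = repeats, seed = seed, balance = balance,
                 standardize = standardize, sbs = sbs,
                 sbs_stop_size = sbs_stop_size, alpha = alpha),
            class = "run_config")
}

#' Run the full mount-detection experiment
#'
#' For each requested frame: builds the window design matrix, balances
#' the classes (shared row selection across frames), grid-searches the
#' SVM cost on a stratified 80% training split, then records the four
#' metrics over `folds x repeats` stratified CV fits on the balanced
#' set. When both frames run, their per-iteration F1 distributions are
#' statistically compared.
#'
#' @param cfg a [run_config()].
#' @param db optional list of [event_recording()]s (overrides
#'   `cfg$db_root`).
#' @return object of class `experiment_bundle`: per-frame list(design,
#'   balanced indices, best_C, cv, confusion, sbs trace) + `comparison` +
#'   `config`.
#' @export
run_experiment <- function(cfg, db = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(db)) {
    if (is.null(cfg$db_root)) stop("run_experiment: no database given")
    db <- read_database(cfg$db_root)
  }
  cm_log("experiment: %d events, frames = %s, seed = %d",
         length(db), paste(cfg$frames, collapse = "+"), cfg$seed)

  frames <- list()
  bal_idx <- NULL
  for (frame in cfg$frames) {
    design <- build_design_matrix(db, frame = frame, window_s = cfg$window_s,
                                  mode = cfg$window_mode)
    X <- design$X; y <- design$y
    if (cfg$balance) {
      if (is.null(bal_idx)) {
        bal <- balance_classes(X, y, stage_seed(cfg$seed, "balance"))
        bal_idx <- bal$idx          # shared across frames: paired design
      }
      X <- X[bal_idx, , drop = FALSE]; y <- y[bal_idx]
    }
    # grid search on a stratified 80% training split
    split_fold <- stratified_folds(y, 5, stage_seed(cfg$seed, "split"))
    train <- which(split_fold != 1)   # 4/5 = 80%
    gs <- grid_search_C(X[train, , drop = FALSE], y[train],
                        grid = cfg$c_grid, folds = cfg$folds,
                        seed = stage_seed(cfg$seed, "grid"),
                        standardize = cfg$standardize)
    cm_log("[%s] grid search: best C = %g", frame, gs$best_C)
    cv <- repeated_stratified_cv(X, y, folds = cfg$folds,
                                 repeats = cfg$repeats, C = gs$best_C,
                                 seed = stage_seed(cfg$seed, "cv"),
                                 standardize = cfg$standardize)
    # per-behavior confusion of a model trained on the balanced set,
    # evaluated on all non-mount windows of the full design
    model <- fit_linear_svm(X, y, gs$best_C, cfg$standardize)
    confusion <- confusion_by_behavior(model, design$X, design$meta$behavior)

    sbs_trace <- NULL
    if (isTRUE(cfg$sbs)) {
      sbs_trace <- sbs(X, y, stop_size = cfg$sbs_stop_size %||% 1,
                       folds = cfg$folds, C = gs$best_C,
                       standardize = cfg$standardize,
                       seed = stage_seed(cfg$seed, "sbs"))
    }
    frames[[frame]] <- list(design = design, balanced_idx = bal_idx,
                            best_C = gs$best_C, grid_scores = gs$scores,
                            cv = cv, confusion = confusion, sbs = sbs_trace)
  }

  comparison <- NULL
  if (all(c("body", "world") %in% names(frames))) {
    comparison <- compare_frames(frames$body$cv$iterations$f1,
                                 frames$world$cv$iterations$f1,
                                 alpha = cfg$alpha)
  } else {
    warning("only one frame requested; no body-vs-world comparison emitted")
  }
  structure(list(frames = frames, comparison = comparison, config = cfg),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> frames: %s\n",
              paste(names(x$frames), collapse = ", ")))
  for (f in names(x$frames)) {
    cat(sprintf("  [%s] C = %g, mean F1 = %.3f\n", f, x$frames[[f]]$best_C,
                mean(x$frames[[f]]$cv$iterations$f1)))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  comparison: %s p = %.3g, rank-biserial %.3f\n",
                x$comparison$test, x$comparison$p, x$comparison$rank_biserial))
  }
  invisible(x)
}

#' Render a text report of an experiment bundle
#'
#' Metric means per frame, F1 descriptive statistics, the per-behavior
#' confusion table, the statistical test block, and (when present) the
#' SBS section.
#'
#' @param bundle an `experiment_bundle`.
#' @return character vector of report lines (also printable via `cat`).
#' @export
reproduce_report <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (!length(bundle$frames)) stop("incomplete bundle: no frame results")
  ln <- c("# Active-mount detection report", "")
  ln <- c(ln, "## Average performance metrics per frame", "")
  for (f in names(bundle$frames)) {
    s <- summary(bundle$frames[[f]]$cv)
    ln <- c(ln, sprintf("### %s frame (C = %g)", f, bundle$frames[[f]]$best_C))
    for (i in seq_len(nrow(s))) {
      ln <- c(ln, sprintf("  %-9s %5.1f%%", s$metric[i], 100 * s$mean[i]))
    }
    ln <- c(ln, sprintf("  F1: mean %.3f, median %.3f, sd %.3f",
                        s$mean[s$metric == "f1"], s$median[s$metric == "f1"],
                        s$sd[s$metric == "f1"]), "")
    conf <- bundle$frames[[f]]$confusion
    if (!is.null(conf) && nrow(conf)) {
      ln <- c(ln, "  False-positive rate per non-mount behavior:")
      for (i in seq_len(nrow(conf))) {
        ln <- c(ln, sprintf("    %-16s n=%3d fp=%3d  %.2f%%", conf$behavior[i],
                            conf$n[i], conf$fp[i], conf$rate_pct[i]))
      }
      ln <- c(ln, "")
    }
    if (!is.null(bundle$frames[[f]]$sbs)) {
      tr <- bundle$frames[[f]]$sbs
      ln <- c(ln, sprintf("  SBS: best F1 %.3f with %d features: %s", tr$best_f1,
                          length(tr$best_subset),
                          paste(tr$best_subset, collapse = ", ")), "")
    }
  }
  if (!is.null(bundle$comparison)) {
    cmp <- bundle$comparison
    ln <- c(ln, "## Body vs world frame comparison", "",
            sprintf("  body : mean %.3f median %.3f sd %.3f",
                    cmp$body["mean"], cmp$body["median"], cmp$body["sd"]),
            sprintf("  world: mean %.3f median %.3f sd %.3f",
                    cmp$world["mean"], cmp$world["median"], cmp$world["sd"]),
            paste0("  ", cmp$decision_path),
            sprintf("  %s: statistic %.4g, p = %.3g, rank-biserial %.3f",
                    cmp$test, cmp$statistic, cmp$p, cmp$rank_biserial),
            sprintf("  mean diff (world - body) %.4g, CI [%.4g, %.4g]",
                    cmp$mean_diff, cmp$ci[1], cmp$ci[2]))
  }
  ln
}
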