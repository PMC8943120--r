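# Per-task random-forest classifiers over the hand-crafted feature banks,
# and the three-way AUC comparison against the CNN.

default_rf_tasks <- function() {
  list(usability       = function(l) l$y1 == 1,
       staining_any    = function(l) l$y3 > 0,
       focus_any       = function(l) l$y4 > 0,
       folding         = function(l) l$y5 == 1,
       other           = function(l) l$y6 == 1,
       staining_severe = function(l) l$y3 == 1,
       focus_severe    = function(l) l$y4 == 1)
}

# Which network output ranks each task (sign-corrected so that higher
# score = positive class).
qnet_task_scores <- function(pred, task) {
  switch(task,
    usability = pred[, "p1"],
    staining_any = pred[, "p3"], staining_severe = pred[, "p3"],
    focus_any = pred[, "p4"], focus_severe = pred[, "p4"],
    folding = pred[, "p5"], other = pred[, "p6"],
    stop("unknown task: ", task, call. = FALSE))
}

#' ROC-AUC of a score against a binary label
#'
#' Higher scores are treated as evidence for the positive class (fixed
#' direction; no automatic flipping).
#'
#' @param labels logical or 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]` (`NA` if only one class is present).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, as.numeric(scores), quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Train one random forest per quality task
#'
#' Fits independent random-forest classifiers (500 trees, class-balanced
#' weights) on a feature table for each label task: usability, staining
#' (any and severe-only), focus (any and severe-only), folding, other.
#' Single-class tasks are skipped with a warning.
#'
#' @param features data frame of features (one row per patch).
#' @param labels data frame with columns `y1`..`y6`.
#' @param tasks named list of label-extractor functions (default: the
#'   seven standard tasks).
#' @param ntree number of trees.
#' @param seed integer seed.
#' @return object of class `rf_bank`: list of `randomForest` fits.
#' @export
train_rf_per_task <- function(features, labels, tasks = default_rf_tasks(),
                              ntree = 500L, seed = 1L) {
  stopifnot(nrow(features) == nrow(labels))
  fits <- list()
  for (nm in names(tasks)) {
    y <- factor(as.integer(tasks[[nm]](labels)), levels = c(0, 1))
    if (length(unique(y[!is.na(y)])) < 2) {
      warning("task '", nm, "' has a single class; skipped", call. = FALSE)
      next
    }
    cw <- 1 / as.numeric(table(y))
    cw <- cw / sum(cw)
    fits[[nm]] <- with_local_seed(seed + match(nm, names(tasks)),
      randomForest::randomForest(x = features, y = y, ntree = ntree,
                                 classwt = setNames(cw, levels(y))))
  }
  structure(list(fits = fits, feature_names = colnames(features)),
            class = "rf_bank")
}

#' @export
print.rf_bank <- function(x, ...) {
  cat(sprintf("<rf_bank> %d task classifiers over %d features: %s\n",
              length(x$fits), length(x$feature_names),
              paste(names(x$fits), collapse = ", ")))
  invisible(x)
}

#' Positive-class probabilities from a task bank
#'
#' @param object an `rf_bank`.
#' @param features data frame of features.
#' @param task task name (one of the bank's fits).
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.rf_bank <- function(object, features, task, ...) {
  fit <- object$fits[[task]]
  if (is.null(fit)) stop("no classifier for task '", task, "'", call. = FALSE)
  as.numeric(predict(fit, features, type = "prob")[, "1"])
}

#' Compare feature banks and the CNN on held-out patches
#'
#' Reproduces the three-way comparison: random forests over the
#' HistoQC-style features, random forests over the "ours" hand-crafted
#' features, and the multi-label network, all evaluated on the same
#' held-out split, one ROC-AUC per task.
#'
#' @param model a fitted [qnet()].
#' @param train,test lists with elements `patches` (list/array) and
#'   `labels` (data frame `y1`..`y6`).
#' @param tasks named list of task definitions.
#' @param seed integer seed for the forests.
#' @return data frame: rows = tasks, columns `histoqc_features`,
#'   `ours_handcrafted`, `quality_net`.
#' @export
compare_banks <- function(model, train, test, tasks = default_rf_tasks(),
                          seed = 1L) {
  f_ours_tr <- feature_table(train$patches, "ours")
  f_ours_te <- feature_table(test$patches, "ours")
  f_hqc_tr <- feature_table(train$patches, "histoqc")
  f_hqc_te <- feature_table(test$patches, "histoqc")
  bank_ours <- suppressWarnings(
    train_rf_per_task(f_ours_tr, train$labels, tasks, seed = seed))
  bank_hqc <- suppressWarnings(
    train_rf_per_task(f_hqc_tr, train$labels, tasks, seed = seed))
  pred <- predict(model, test$patches)
  out <- data.frame(task = names(tasks), histoqc_features = NA_real_,
                    ours_handcrafted = NA_real_, quality_net = NA_real_)
  for (i in seq_along(tasks)) {
    nm <- names(tasks)[i]
    y <- as.integer(tasks[[nm]](test$labels))
    if (length(unique(y)) < 2) next
    if (!is.null(bank_hqc$fits[[nm]]))
      out$histoqc_features[i] <- roc_auc(y, predict(bank_hqc, f_hqc_te, nm))
    if (!is.null(bank_ours$fits[[nm]]))
      out$ours_handcrafted[i] <- roc_auc(y, predict(bank_ours, f_ours_te, nm))
    out$quality_net[i] <- roc_auc(y, qnet_task_scores(pred, nm))
  }
  out
}
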