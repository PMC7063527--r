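# Evaluation: confusion counts, precision/recall/accuracy/F1, negative-class
# F1, Cohen kappa inter-annotator agreement, and leave-one-feature-group-out
# ablation.

# round half up at `digits` decimals (display convention for reports)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion matrix for binary labels
#'
#' @param y_true,y_pred equal-length binary label vectors (0/1, logical, or
#'   "negative"/"positive").
#' @return object of class `confusion_matrix`: list with integer fields
#'   `tp`, `fp`, `tn`, `fn` summing to `length(y_true)`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  yt <- as_label_factor(y_true)
  yp <- as_label_factor(y_pred)
  structure(
    list(tp = sum(yt == "positive" & yp == "positive"),
         fp = sum(yt == "negative" & yp == "positive"),
         tn = sum(yt == "negative" & yp == "negative"),
         fn = sum(yt == "positive" & yp == "negative")),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (n =", x$tp + x$fp + x$tn + x$fn, ")\n")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * precision * recall / (precision + recall)`; 0 when
#' both are 0.
#'
#' @param precision,recall numeric in [0, 1].
#' @return numeric F1 in [0, 1].
#' @examples
#' f1_score(0.926, 0.388)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Classification metrics from a confusion matrix
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, positive-class F1, and the negative-class F1
#' (obtained by treating the negative class as the class of interest).
#' Ratios with a zero denominator are reported as 0 and flagged in
#' `undefined`.
#'
#' @param cm a `confusion_matrix` from [confusion()].
#' @return object of class `metrics_report`: list with `precision`,
#'   `recall`, `accuracy`, `f1_positive`, `f1_negative` (full precision)
#'   and `undefined` (character vector of metrics with zero denominators).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  accuracy <- ratio(cm$tp + cm$tn, n, "accuracy")
  # negative class as the class of interest
  precision_neg <- ratio(cm$tn, cm$tn + cm$fn, "precision_negative")
  recall_neg <- ratio(cm$tn, cm$tn + cm$fp, "recall_negative")
  structure(
    list(precision = precision, recall = recall, accuracy = accuracy,
         f1_positive = f1_score(precision, recall),
         f1_negative = f1_score(precision_neg, recall_neg),
         undefined = undefined),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "precision %.3f  recall %.3f  accuracy %.3f  F1+ %.3f  F1- %.3f\n",
    round_half_up(x$precision, digits), round_half_up(x$recall, digits),
    round_half_up(x$accuracy, digits), round_half_up(x$f1_positive, digits),
    round_half_up(x$f1_negative, digits)))
  if (length(x$undefined) > 0L) {
    cat("  undefined (reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohen kappa inter-annotator agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' binary annotations, with expected agreement `p_e` from the product of the
#' annotators' marginals. When both annotators give identical constant
#' labels (`p_e = 1`), agreement is perfect and kappa is defined as 1.
#'
#' @param ann_a,ann_b equal-length binary label vectors.
#' @return object of class `agreement_result`: list with `kappa`,
#'   `observed` (p_o), `expected` (p_e), `n`.
#' @examples
#' cohen_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0))
#' @export
cohen_kappa <- function(ann_a, ann_b) {
  if (length(ann_a) != length(ann_b)) {
    stop("annotations must have equal length")
  }
  if (length(ann_a) == 0L) stop("annotations are empty")
  a <- as_label_factor(ann_a)
  b <- as_label_factor(ann_b)
  n <- length(a)
  p_o <- mean(a == b)
  pa <- mean(a == "positive")
  pb <- mean(b == "positive")
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else stop("expected agreement is 1 but annotations differ")
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa, observed = p_o, expected = p_e, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen kappa %.3f (observed %.3f, expected %.3f, n = %d)\n",
              round_half_up(x$kappa, 3L), x$observed, x$expected, x$n))
  invisible(x)
}

# gold-label column for a task
task_label_column <- function(task) {
  switch(match.arg(task, c("nonmedical", "side_effects")),
         nonmedical = "gold_nonmedical",
         side_effects = "gold_side_effects")
}

#' Tune, fit and evaluate one task classifier
#'
#' Convenience wrapper: selects the task's feature columns, tunes
#' (cost, gamma) by stratified cross-validated grid search, computes pooled
#' out-of-fold metrics at the chosen point, and fits the final model on all
#' rows.
#'
#' @param features featurized corpus data frame with gold labels
#'   (see [featurize_corpus()]).
#' @param task `"nonmedical"` or `"side_effects"`.
#' @param config an [svm_config()].
#' @param registry a `lexicon_registry`.
#' @param exclude_columns feature columns to drop before training (used by
#'   the ablation).
#' @return list with `model` (a `tweet_svm`), `tuning` (from
#'   [tune_hyperparameters()]), `metrics` (pooled-CV `metrics_report`),
#'   `cv_predictions` (0/1, aligned with rows), `confusion`.
#' @export
train_and_evaluate <- function(features, task, config = svm_config(),
                               registry = load_default_lexicons(),
                               exclude_columns = character(0)) {
  label_col <- task_label_column(task)
  if (!label_col %in% names(features)) {
    stop("gold labels '", label_col, "' missing from features")
  }
  y <- features[[label_col]]
  if (any(is.na(y))) stop("gold labels contain NA")
  X <- select_task_features(features, task, registry)
  if (length(exclude_columns) > 0L) {
    unknown <- setdiff(exclude_columns, colnames(X))
    if (length(unknown) > 0L) {
      stop("cannot exclude columns absent from the '", task, "' task: ",
           paste(unknown, collapse = ", "))
    }
    X <- X[, setdiff(colnames(X), exclude_columns), drop = FALSE]
  }
  tuning <- tune_hyperparameters(X, y, config)
  cv_pred <- cv_pooled_predictions(X, y, tuning$cost, tuning$gamma, config)
  cm <- confusion(y, cv_pred)
  model <- fit_classifier(X, y, tuning$cost, tuning$gamma, config,
                          task = task,
                          lexicon_version = registry$version)
  list(model = model, tuning = tuning, metrics = classification_metrics(cm),
       cv_predictions = cv_pred, confusion = cm)
}

#' Leave-one-feature-group-out ablation
#'
#' Trains the full task model, then retrains once per feature group with
#' that group's columns removed before scaling, each run with its own
#' hyperparameter tuning. All rows are evaluated with pooled out-of-fold
#' predictions on the same seed-fixed folds, so rows are comparable.
#'
#' @inheritParams train_and_evaluate
#' @return object of class `ablation_report`: a data frame with one
#'   `final_model` row and one `without_<group>` row per feature group,
#'   columns `model`, `f1_positive`, `f1_negative`, `precision`, `recall`,
#'   `accuracy` (full precision), plus attributes `task` and `tunings`.
#' @export
run_ablation <- function(features, task, config = svm_config(),
                         registry = load_default_lexicons()) {
  groups <- feature_groups(task, registry)
  runs <- c(list(final_model = character(0)),
            stats::setNames(groups, paste0("without_", names(groups))))
  tunings <- list()
  rows <- lapply(names(runs), function(label) {
    res <- train_and_evaluate(features, task, config, registry,
                              exclude_columns = runs[[label]])
    tunings[[label]] <<- res$tuning[c("cost", "gamma", "cv_f1")]
    m <- res$metrics
    data.frame(model = label, f1_positive = m$f1_positive,
               f1_negative = m$f1_negative, precision = m$precision,
               recall = m$recall, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "task") <- task
  attr(out, "tunings") <- tunings
  class(out) <- c("ablation_report", "data.frame")
  out
}

#' @export
print.ablation_report <- function(x, digits = 3L, ...) {
  cat("Feature-group ablation [", attr(x, "task"), "] ",
      "(pooled cross-validated metrics)\n", sep = "")
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round_half_up, digits = digits)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Write an ablation report
#'
#' CSV mirrors the report table (metrics rounded half-up to 3 decimals);
#' JSON carries full precision plus the per-row tuning choices.
#'
#' @param report an `ablation_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the paths written.
#' @export
write_ablation_report <- function(report, csv_path = NULL,
                                  json_path = NULL) {
  stopifnot(inherits(report, "ablation_report"))
  written <- list()
  if (!is.null(csv_path)) {
    disp <- as.data.frame(report)
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], round_half_up, digits = 3L)
    utils::write.csv(disp, csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(task = attr(report, "task"),
           rows = as.data.frame(report),
           tunings = attr(report, "tunings")),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written$json <- json_path
  }
  invisible(written)
}
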