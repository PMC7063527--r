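# Class-weighted RBF-SVM classifiers: standardization, inverse class
# weights, stratified cross-validated grid search over (cost, gamma),
# fitting and prediction. The SVM solver is e1071/libsvm; everything around
# it (weights, scaling, folds, selection, tie-breaking) is defined here.

#' SVM training configuration
#'
#' @param cost_grid positive reals; default powers of two `2^(-2..10)`.
#' @param gamma_grid positive reals; default powers of two `2^(-9..1)`.
#' @param cv_folds number of stratified cross-validation folds (>= 2).
#' @param seed integer seed fixing fold assignment.
#' @return object of class `svm_config`. Kernel is fixed to the radial
#'   basis function, class weighting to inverse class frequency, and
#'   feature scaling to standardization; these are not tunable.
#' @export
svm_config <- function(cost_grid = 2^seq(-2, 10),
                       gamma_grid = 2^seq(-9, 1),
                       cv_folds = 10L, seed = 42L) {
  stopifnot(length(cost_grid) > 0L, all(cost_grid > 0),
            length(gamma_grid) > 0L, all(gamma_grid > 0),
            cv_folds >= 2L, is.numeric(seed))
  structure(
    list(kernel = "rbf", cost_grid = sort(cost_grid),
         gamma_grid = sort(gamma_grid), cv_folds = as.integer(cv_folds),
         class_weighting = "inverse", scaling = "standardize",
         seed = as.integer(seed)),
    class = "svm_config"
  )
}

# normalize labels to a factor with levels negative < positive
as_label_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  if (is.numeric(y) || is.integer(y)) {
    if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
    y <- ifelse(y == 1, "positive", "negative")
  }
  if (!all(y %in% c("negative", "positive"))) {
    stop("labels must be 0/1 or 'negative'/'positive'")
  }
  factor(y, levels = c("negative", "positive"))
}

#' Inverse class weights
#'
#' Per-class weights `w_c = N / (2 * n_c)`, which equalize the total weighted
#' mass of the two classes and compensate for the heavy negative-class
#' imbalance typical of drug-mention tweet corpora.
#'
#' @param y binary labels (0/1, logical, or "negative"/"positive").
#' @return named numeric vector `c(negative = ..., positive = ...)`.
#' @examples
#' compute_class_weights(c(rep(1, 10), rep(0, 90)))
#' @export
compute_class_weights <- function(y) {
  yf <- as_label_factor(y)
  n <- table(yf)
  if (any(n == 0L)) {
    stop("both classes must be present; found only '",
         names(n)[n > 0L], "'")
  }
  w <- length(yf) / (2 * as.numeric(n))
  names(w) <- names(n)
  w
}

# stratified fold assignment, deterministic given seed
make_folds <- function(y, k, seed) {
  yf <- as_label_factor(y)
  if (any(table(yf) == 0L)) {
    stop("both classes must be present in y")
  }
  folds <- integer(length(yf))
  set.seed(seed)
  for (cls in levels(yf)) {
    idx <- which(yf == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (!any(yf[folds == f] == "positive")) {
      stop("fold ", f, " contains no positive examples; ",
           "reduce cv_folds or enlarge the corpus")
    }
  }
  folds
}

# standardization parameters from training data; zero-spread columns pass
# through unscaled (center 0, scale 1)
scaling_params <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- !is.finite(scl) | scl == 0
  ctr[const] <- 0
  scl[const] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(X, sp) {
  sweep(sweep(X, 2, sp$center, "-"), 2, sp$scale, "/")
}

# positive-class F1 from labels; undefined ratios count as 0
fold_f1 <- function(y_true, y_pred) {
  tp <- sum(y_true == "positive" & y_pred == "positive")
  fp <- sum(y_true == "negative" & y_pred == "positive")
  fn <- sum(y_true == "positive" & y_pred == "negative")
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# precompute per-fold scaled training/test sets and weights
prepare_folds <- function(X, yf, folds) {
  lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    sp <- scaling_params(X[tr, , drop = FALSE])
    list(
      Xtr = apply_scaling(X[tr, , drop = FALSE], sp),
      Xte = apply_scaling(X[!tr, , drop = FALSE], sp),
      ytr = yf[tr], yte = yf[!tr],
      weights = compute_class_weights(yf[tr])
    )
  })
}

svm_fit_raw <- function(Xs, yf, cost, gamma, weights) {
  svm(x = Xs, y = yf, type = "C-classification", kernel = "radial",
      cost = cost, gamma = gamma, class.weights = weights, scale = FALSE)
}

#' Tune SVM cost and gamma by stratified cross-validated grid search
#'
#' Exhaustive search over `cost_grid` x `gamma_grid`. Folds are stratified
#' by label and fixed by the configuration seed; the selection metric is the
#' mean positive-class F1 across folds (folds where the model predicts no
#' positives contribute F1 = 0). Ties are broken toward the smaller cost,
#' then the smaller gamma.
#'
#' @param X numeric feature matrix (rows = tweets).
#' @param y binary labels.
#' @param config an [svm_config()].
#' @return list with `cost`, `gamma`, `cv_f1` (mean F1 of the winner) and
#'   `grid` (data frame of all grid points with their mean CV F1).
#' @export
tune_hyperparameters <- function(X, y, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values in X")
  yf <- as_label_factor(y)
  if (length(yf) < config$cv_folds) {
    stop("need at least cv_folds observations")
  }
  if (length(config$cost_grid) == 0L || length(config$gamma_grid) == 0L) {
    stop("hyperparameter grid is empty")
  }
  folds <- make_folds(yf, config$cv_folds, config$seed)
  fold_data <- prepare_folds(X, yf, folds)
  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    f1s <- vapply(fold_data, function(fd) {
      fit <- svm_fit_raw(fd$Xtr, fd$ytr, grid$cost[i], grid$gamma[i],
                         fd$weights)
      pred <- stats::predict(fit, fd$Xte)
      fold_f1(fd$yte, pred)
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  # max F1; ties toward smaller cost, then smaller gamma
  ord <- order(-grid$cv_f1, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  list(cost = best$cost, gamma = best$gamma, cv_f1 = best$cv_f1,
       grid = grid)
}

#' Fit a class-weighted RBF-SVM classifier
#'
#' Standardizes features with training-set statistics (constant columns pass
#' through unscaled), applies inverse class weights, and fits a radial
#' basis function SVM at the given cost and gamma. Classification is by the
#' sign of the decision value; there is no probability calibration.
#'
#' @param X numeric feature matrix (rows = tweets, named columns).
#' @param y binary labels.
#' @param cost,gamma RBF-SVM hyperparameters, e.g. from
#'   [tune_hyperparameters()].
#' @param config an [svm_config()] (recorded in the object).
#' @param task optional task tag ("nonmedical" or "side_effects").
#' @param lexicon_version version string of the registry the features came
#'   from; predictions are refused if a different version is supplied later.
#' @return object of class `tweet_svm`.
#' @seealso [predict.tweet_svm()], [tune_hyperparameters()]
#' @export
fit_classifier <- function(X, y, cost, gamma, config = svm_config(),
                           task = NULL, lexicon_version = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values in X")
  stopifnot(cost > 0, gamma > 0)
  yf <- as_label_factor(y)
  weights <- compute_class_weights(yf)
  sp <- scaling_params(X)
  fit <- svm_fit_raw(apply_scaling(X, sp), yf, cost, gamma, weights)
  structure(
    list(task = task, cost = cost, gamma = gamma, class_weights = weights,
         center = sp$center, scale = sp$scale, model = fit,
         feature_names = colnames(X), n_train = nrow(X),
         class_counts = as.integer(table(yf)), config = config,
         lexicon_version = lexicon_version),
    class = "tweet_svm"
  )
}

#' Predict binary labels with a fitted classifier
#'
#' @param object a `tweet_svm` from [fit_classifier()].
#' @param newdata numeric matrix whose columns match the training feature
#'   order (reordered by name when named).
#' @param lexicon_version optional registry version of the features;
#'   must equal the version recorded at training time.
#' @param ... unused.
#' @return integer vector of 0/1 labels (1 = positive).
#' @export
predict.tweet_svm <- function(object, newdata, lexicon_version = NULL, ...) {
  if (!is.null(lexicon_version) && !is.null(object$lexicon_version) &&
      !identical(lexicon_version, object$lexicon_version)) {
    stop("lexicon version mismatch: model trained with '",
         object$lexicon_version, "', features built with '",
         lexicon_version, "'")
  }
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(integer(0))
  if (ncol(newdata) != length(object$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(object$feature_names), " columns, got ", ncol(newdata))
  }
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    if (!setequal(colnames(newdata), object$feature_names)) {
      stop("feature columns do not match the model's feature ordering")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  Xs <- apply_scaling(newdata, list(center = object$center,
                                    scale = object$scale))
  pred <- stats::predict(object$model, Xs)
  as.integer(pred == "positive")
}

#' Pooled out-of-fold predictions
#'
#' Fits the classifier at fixed (cost, gamma) on each training fold and
#' predicts its held-out fold, pooling predictions over all folds. This is
#' the default protocol for reported performance: every tweet is predicted
#' by a model that did not see it.
#'
#' @inheritParams tune_hyperparameters
#' @param cost,gamma hyperparameters to use in every fold.
#' @return integer vector of 0/1 out-of-fold predictions aligned with `y`.
#' @export
cv_pooled_predictions <- function(X, y, cost, gamma, config = svm_config()) {
  X <- as.matrix(X)
  yf <- as_label_factor(y)
  folds <- make_folds(yf, config$cv_folds, config$seed)
  pred <- integer(length(yf))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sp <- scaling_params(X[tr, , drop = FALSE])
    fit <- svm_fit_raw(apply_scaling(X[tr, , drop = FALSE], sp), yf[tr],
                       cost, gamma, compute_class_weights(yf[tr]))
    p <- stats::predict(fit, apply_scaling(X[!tr, , drop = FALSE], sp))
    pred[!tr] <- as.integer(p == "positive")
  }
  pred
}

#' Save / load a fitted classifier
#'
#' The persisted file embeds the configuration, scaling parameters, feature
#' ordering and lexicon version, so a reloaded model refuses features built
#' against a different lexicon version.
#'
#' @param object a `tweet_svm`.
#' @param path file path.
#' @return `path` invisibly (save); a `tweet_svm` (load).
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "tweet_svm"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "tweet_svm")) stop("not a saved tweet_svm: ", path)
  object
}

#' @export
print.tweet_svm <- function(x, ...) {
  cat("Class-weighted RBF-SVM tweet classifier",
      if (!is.null(x$task)) paste0(" [", x$task, "]"), "\n", sep = "")
  cat(sprintf("  cost = %g, gamma = %g\n", x$cost, x$gamma))
  cat(sprintf("  trained on %d tweets (%d negative / %d positive)\n",
              x$n_train, x$class_counts[1], x$class_counts[2]))
  cat(sprintf("  class weights: negative %.4f, positive %.4f\n",
              x$class_weights[["negative"]], x$class_weights[["positive"]]))
  invisible(x)
}

#' @export
summary.tweet_svm <- function(object, ...) {
  print(object)
  cat("  features (", length(object$feature_names), "): ",
      paste(object$feature_names, collapse = ", "), "\n", sep = "")
  if (!is.null(object$lexicon_version)) {
    cat("  lexicon version:", object$lexicon_version, "\n")
  }
  cat("  support vectors:", object$model$tot.nSV, "\n")
  invisible(object)
}
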