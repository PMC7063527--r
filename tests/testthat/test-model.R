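# Class weights, grid-search tuning, fitting and prediction.

test_that("inverse class weights equalize class mass", {
  w <- compute_class_weights(c(rep(1, 50), rep(0, 50)))
  expect_equal(unname(w), c(1, 1))
  w2 <- compute_class_weights(c(rep(1, 10), rep(0, 90)))
  expect_equal(w2[["positive"]], 5)
  expect_equal(w2[["negative"]], 0.5556, tolerance = 1e-3)
  expect_equal(10 * w2[["positive"]], 90 * w2[["negative"]])
  expect_error(compute_class_weights(rep(0, 100)), "both classes")
})

test_that("tuning returns forced grid points and breaks ties toward the smaller cost", {
  feats <- test_features(n = 200L, seed = 13L)
  X <- select_task_features(feats, "nonmedical")
  y <- feats$gold_nonmedical
  one <- tune_hyperparameters(X, y, svm_config(cost_grid = 4,
                                               gamma_grid = 0.125,
                                               cv_folds = 5, seed = 2))
  expect_equal(one$cost, 4)
  expect_equal(one$gamma, 0.125)
  expect_equal(nrow(one$grid), 1L)

  # separable data: several grid points reach the same CV F1; smaller cost,
  # then smaller gamma, wins
  set.seed(9)
  Xs <- cbind(x1 = c(rnorm(60, -3), rnorm(60, 3)),
              x2 = rnorm(120))
  ys <- rep(c(0, 1), each = 60)
  tie <- tune_hyperparameters(Xs, ys, svm_config(cost_grid = c(1, 16),
                                                 gamma_grid = c(0.5, 0.125),
                                                 cv_folds = 5, seed = 2))
  best_f1 <- max(tie$grid$cv_f1)
  ties <- tie$grid[tie$grid$cv_f1 == best_f1, ]
  expect_gt(nrow(ties), 1L)
  expect_equal(tie$cost, min(ties$cost))
  expect_equal(tie$gamma,
               min(ties$gamma[ties$cost == tie$cost]))

  expect_error(tune_hyperparameters(X[1:5, ], y[1:5],
                                    svm_config(cv_folds = 10)),
               "cv_folds")
})

test_that("strong injected signal reaches cross-validated F1 >= 0.9 at n = 400", {
  feats <- test_features(n = 400L, seed = 7L)
  X <- select_task_features(feats, "nonmedical")
  tun <- tune_hyperparameters(X, feats$gold_nonmedical,
                              coarse_config(seed = 1, cv_folds = 5))
  expect_gte(tun$cv_f1, 0.9)
})

test_that("fitting is deterministic, separates the training set, and tolerates constant columns", {
  feats <- test_features(n = 400L, seed = 7L)
  X <- select_task_features(feats, "nonmedical")
  y <- feats$gold_nonmedical
  clf <- fit_classifier(X, y, cost = 16, gamma = 0.125, task = "nonmedical")
  pred <- predict(clf, X)
  m <- classification_metrics(confusion(y, pred))
  expect_gte(m$f1_positive, 0.95)

  clf2 <- fit_classifier(X, y, cost = 16, gamma = 0.125)
  probe <- X[sample.int(nrow(X), 50), , drop = FALSE]
  expect_identical(predict(clf, probe), predict(clf2, probe))

  Xc <- cbind(X, constant = 1)
  clf3 <- fit_classifier(Xc, y, cost = 16, gamma = 0.125)
  expect_length(predict(clf3, Xc), nrow(Xc))
  expect_equal(unname(clf3$scale[["constant"]]), 1)

  Xbad <- X
  Xbad[1, 1] <- NA
  expect_error(fit_classifier(Xbad, y, 16, 0.125), "non-finite")
})

test_that("prediction follows training geometry and validates its inputs", {
  feats <- test_features(n = 400L, seed = 7L)
  X <- select_task_features(feats, "nonmedical")
  y <- feats$gold_nonmedical
  clf <- fit_classifier(X, y, cost = 16, gamma = 0.125,
                        lexicon_version = "mph-1.0")
  # training positives with heavy class weight are recovered
  pos_idx <- which(y == 1)
  expect_gte(mean(predict(clf, X[pos_idx, , drop = FALSE]) == 1), 0.9)
  # all-zero rows were overwhelmingly negative in training
  zero <- X[rowSums(X) == 0, , drop = FALSE]
  expect_true(all(predict(clf, zero[1, , drop = FALSE]) == 0))
  expect_identical(predict(clf, X[0, , drop = FALSE]), integer(0))
  expect_error(predict(clf, X[, 1:5]), "dimension")
  expect_error(predict(clf, X, lexicon_version = "other-2.0"), "mismatch")

  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  expect_identical(predict(load_classifier(path), X[1:20, ]),
                   predict(clf, X[1:20, ]))
})

test_that("with balanced classes, inverse weighting equals unweighted training", {
  set.seed(31)
  Xb <- cbind(x1 = c(rnorm(40, -1), rnorm(40, 1)), x2 = rnorm(80))
  yb <- rep(c(0, 1), each = 40)
  w <- compute_class_weights(yb)
  expect_equal(unname(w), c(1, 1))
  clf_w <- fit_classifier(Xb, yb, cost = 2, gamma = 0.5)
  unweighted <- e1071::svm(x = scale(Xb), y = factor(ifelse(yb == 1,
    "positive", "negative"), levels = c("negative", "positive")),
    type = "C-classification", kernel = "radial", cost = 2, gamma = 0.5,
    scale = FALSE)
  probe <- Xb
  expect_identical(predict(clf_w, probe),
                   as.integer(predict(unweighted, scale(probe,
                     center = attr(scale(Xb), "scaled:center"),
                     scale = attr(scale(Xb), "scaled:scale"))) == "positive"))
})

test_that("without weighting, minority recall does not rise as imbalance grows", {
  recall_at <- function(p_pos) {
    set.seed(55)
    n <- 400L
    n_pos <- round(p_pos * n)
    X <- cbind(x1 = c(rnorm(n - n_pos, 0), rnorm(n_pos, 1.2)),
               x2 = rnorm(n))
    y <- factor(c(rep("negative", n - n_pos), rep("positive", n_pos)),
                levels = c("negative", "positive"))
    fit <- e1071::svm(x = X, y = y, type = "C-classification",
                      kernel = "radial", cost = 1, gamma = 0.5)
    pred <- predict(fit, X)
    sum(pred == "positive" & y == "positive") / sum(y == "positive")
  }
  r <- vapply(c(0.30, 0.15, 0.05), recall_at, numeric(1))
  expect_true(r[2] <= r[1] + 1e-9)
  expect_true(r[3] <= r[2] + 1e-9)
})
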