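# Confusion counts, metric identities, Cohen kappa, and the ablation runner.

test_that("confusion counts enumerate correctly and preserve totals", {
  cm <- confusion(c(1, 0), c(1, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cm2 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  cm3 <- confusion(rep(0, 7), rep(0, 7))
  expect_equal(cm3$tn, 7L)
  expect_equal(cm3$tp + cm3$fp + cm3$fn, 0L)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics match a brute-force recount on random label pairs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    y_true <- stats::rbinom(n, 1, runif(1, 0.1, 0.9))
    y_pred <- stats::rbinom(n, 1, runif(1, 0.1, 0.9))
    m <- classification_metrics(confusion(y_true, y_pred))
    # independent recount straight from the labels
    tp <- sum(y_true == 1 & y_pred == 1)
    fp <- sum(y_true == 0 & y_pred == 1)
    fn <- sum(y_true == 1 & y_pred == 0)
    tn <- sum(y_true == 0 & y_pred == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    expect_equal(m$accuracy, (tp + tn) / n)
    expect_equal(m$f1_positive,
                 if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    prec_n <- if (tn + fn > 0) tn / (tn + fn) else 0
    rec_n <- if (tn + fp > 0) tn / (tn + fp) else 0
    expect_equal(m$f1_negative,
                 if (prec_n + rec_n > 0)
                   2 * prec_n * rec_n / (prec_n + rec_n) else 0)
  }
})

test_that("undefined ratios report 0 with a flag; perfect matrices score 1", {
  none_pred <- classification_metrics(confusion(c(1, 0, 0), c(0, 0, 0)))
  expect_equal(none_pred$precision, 0)
  expect_true("precision" %in% none_pred$undefined)
  perfect <- classification_metrics(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_positive, 1)
  expect_equal(perfect$f1_negative, 1)
  expect_length(perfect$undefined, 0L)
})

test_that("Cohen kappa matches the closed form on 2x2 tables", {
  expect_equal(cohen_kappa(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1))$kappa, 1)
  k0 <- cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(k0$kappa, 0)
  expect_equal(k0$observed, 0.5)
  expect_equal(k0$expected, 0.5)
  k5 <- cohen_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0))
  expect_equal(k5$kappa, 0.5)
  # symmetric in its arguments; invariant under in-tandem permutation
  set.seed(5)
  a <- stats::rbinom(40, 1, 0.3)
  b <- stats::rbinom(40, 1, 0.4)
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  perm <- sample.int(40)
  expect_equal(cohen_kappa(a[perm], b[perm])$kappa, cohen_kappa(a, b)$kappa)
  # enumerated degenerate tables
  expect_equal(cohen_kappa(rep(1, 4), rep(1, 4))$kappa, 1)
  expect_equal(cohen_kappa(rep(1, 4), rep(0, 4))$kappa, 0)
  expect_equal(cohen_kappa(c(1, 0), c(0, 1))$kappa, -1)
  expect_error(cohen_kappa(c(1, 0), c(1)), "equal length")
})

test_that("ablation produces one row per feature group plus the final model", {
  feats <- test_features(n = 300L, seed = 17L)
  cfg <- point_config(seed = 4, cv_folds = 5)
  rep_nm <- run_ablation(feats, "nonmedical", cfg)
  expect_s3_class(rep_nm, "ablation_report")
  expect_identical(rep_nm$model,
                   c("final_model", "without_nonmedical_use_terms",
                     "without_medical_use_terms", "without_personal_noun",
                     "without_sentiment_scores", "without_url"))
  # full-model row equals a direct tune+fit+evaluate run with the same seed
  direct <- train_and_evaluate(feats, "nonmedical", cfg)
  expect_equal(rep_nm$f1_positive[1], direct$metrics$f1_positive)
  expect_equal(rep_nm$precision[1], direct$metrics$precision)

  rep_se <- run_ablation(feats, "side_effects", cfg)
  expect_identical(rep_se$model[1:2],
                   c("final_model", "without_side_effect_terms"))
  expect_equal(nrow(rep_se), 5L)

  # excluding a group absent from the task is a contract violation
  expect_error(train_and_evaluate(feats, "nonmedical", cfg,
                                  exclude_columns = "se_general"),
               "absent")

  paths <- withr::local_tempfile(fileext = c(".csv", ".json"))
  write_ablation_report(rep_nm, paths[1], paths[2])
  csv <- utils::read.csv(paths[1])
  expect_equal(nrow(csv), 6L)
  expect_equal(csv$f1_positive,
               unname(vapply(rep_nm$f1_positive, function(x)
                 floor(x * 1000 + 0.5) / 1000, numeric(1))))
})
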