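# Corpus-level orchestration: JSON-lines I/O, deduplication, search-term
# filtering, train/test splitting, percentage summaries, monthly trends and
# the end-to-end pipeline.

#' Read / write a tweet corpus as JSON lines
#'
#' One JSON object per line: `{"id": ..., "created_at": ISO-8601 UTC,
#' "text": ..., "labels": {"nonmedical": 0/1, "side_effects": 0/1}}`
#' (`labels` optional).
#'
#' @param path file path.
#' @return corpus data frame with columns `tweet_id`, `created_at`
#'   (POSIXct, UTC), `text`, and (when labels are present)
#'   `gold_nonmedical`, `gold_side_effects`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(tweet_id = character(0),
                      created_at = as.POSIXct(character(0), tz = "UTC"),
                      text = character(0), stringsAsFactors = FALSE))
  }
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  get <- function(r, field) if (is.null(r[[field]])) NA else r[[field]]
  out <- data.frame(
    tweet_id = vapply(recs, function(r) as.character(get(r, "id")), ""),
    created_at = as.POSIXct(
      vapply(recs, function(r) as.character(get(r, "created_at")), ""),
      tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"),
    text = vapply(recs, function(r) as.character(get(r, "text")), ""),
    stringsAsFactors = FALSE
  )
  labs <- lapply(recs, `[[`, "labels")
  if (any(!vapply(labs, is.null, logical(1)))) {
    lab_val <- function(l, field) {
      if (is.null(l) || is.null(l[[field]])) NA_integer_ else
        as.integer(l[[field]])
    }
    out$gold_nonmedical <- vapply(labs, lab_val, integer(1), "nonmedical")
    out$gold_side_effects <- vapply(labs, lab_val, integer(1),
                                    "side_effects")
  }
  if (anyDuplicated(out$tweet_id)) {
    stop("duplicate tweet ids in corpus: ",
         paste(unique(out$tweet_id[duplicated(out$tweet_id)])[1:5],
               collapse = ", "))
  }
  if (any(!nzchar(trimws(out$text)))) {
    stop("corpus contains tweets with empty text")
  }
  out
}

#' @rdname read_corpus_jsonl
#' @param tweets corpus data frame.
#' @export
write_corpus_jsonl <- function(tweets, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  has_labels <- all(c("gold_nonmedical", "gold_side_effects") %in%
                      names(tweets))
  for (i in seq_len(nrow(tweets))) {
    rec <- list(
      id = tweets$tweet_id[i],
      created_at = format(tweets$created_at[i], "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC"),
      text = tweets$text[i]
    )
    if (has_labels && !is.na(tweets$gold_nonmedical[i])) {
      rec$labels <- list(nonmedical = tweets$gold_nonmedical[i],
                         side_effects = tweets$gold_side_effects[i])
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Remove duplicate tweets
#'
#' Tweets whose whitespace-normalized, case-folded text matches an earlier
#' tweet are removed; among duplicates the earliest timestamp survives
#' (first occurrence on ties). Output preserves the input order of the
#' survivors.
#'
#' @param tweets corpus data frame.
#' @return deduplicated corpus data frame.
#' @export
dedupe <- function(tweets) {
  if (nrow(tweets) == 0L) return(tweets)
  key <- tolower(gsub("[[:space:]]+", " ", trimws(tweets$text)))
  ts <- if ("created_at" %in% names(tweets)) {
    as.numeric(tweets$created_at)
  } else {
    seq_len(nrow(tweets))
  }
  ts[is.na(ts)] <- Inf
  keep <- vapply(split(seq_len(nrow(tweets)), key), function(idx) {
    idx[which.min(ts[idx])]
  }, integer(1))
  tweets[sort(unname(keep)), , drop = FALSE]
}

#' Filter tweets by drug-name search terms
#'
#' Keeps tweets whose text contains any term as a case-insensitive
#' substring, mirroring collection-time drug-name search (so a term inside
#' a longer word also matches).
#'
#' @param tweets corpus data frame.
#' @param terms character vector; defaults to [default_search_terms()].
#' @return filtered corpus data frame.
#' @export
filter_search_terms <- function(tweets, terms = default_search_terms()) {
  stopifnot(length(terms) > 0L)
  if (nrow(tweets) == 0L) return(tweets)
  text <- tolower(tweets$text)
  hit <- rep(FALSE, length(text))
  for (term in tolower(terms)) {
    hit <- hit | grepl(term, text, fixed = TRUE)
  }
  tweets[hit, , drop = FALSE]
}

#' Random train/test split
#'
#' Simple random sample without replacement; `round(fraction * N)` tweets
#' (or exactly `train_size` when given) form the training set. Deterministic
#' given the seed; the two parts partition the input.
#'
#' @param tweets corpus data frame (N >= 2).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @param train_size optional exact training-set size, overriding
#'   `fraction` (reproduces externally reported split sizes).
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(tweets, fraction = 0.2, seed = 1L,
                             train_size = NULL) {
  n <- nrow(tweets)
  if (n < 2L) stop("need at least 2 tweets to split")
  if (is.null(train_size)) {
    stopifnot(fraction > 0, fraction < 1)
    train_size <- round(fraction * n)
  }
  train_size <- as.integer(train_size)
  if (train_size < 1L || train_size >= n) {
    stop("train_size must be in [1, N-1]")
  }
  set.seed(seed)
  idx <- sort(sample.int(n, train_size))
  list(train = tweets[idx, , drop = FALSE],
       test = tweets[-idx, , drop = FALSE])
}

#' Percentage with report rounding
#'
#' `100 * numerator / denominator`, rounded half-up to 2 decimals — the
#' display convention for all corpus percentages.
#'
#' @param numerator,denominator numbers; `denominator > 0`.
#' @return numeric percentage (2 decimals).
#' @examples
#' percent(356, 6860)
#' @export
percent <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, 2L)
}

#' Monthly trend of positive classifications
#'
#' Buckets tweets by UTC calendar month and reports per-month totals,
#' positive counts and the positive percentage (2 decimals). Months with no
#' tweets are omitted; rows are sorted chronologically.
#'
#' @param tweets corpus data frame with `created_at`.
#' @param positive 0/1 vector aligned with `tweets` rows (e.g. classifier
#'   predictions).
#' @return object of class `monthly_trend`: data frame with columns
#'   `month` ("YYYY-MM"), `n_total`, `n_positive`, `percent`.
#' @export
monthly_trend <- function(tweets, positive) {
  stopifnot(nrow(tweets) == length(positive),
            "created_at" %in% names(tweets))
  positive <- as.integer(positive)
  month <- format(tweets$created_at, "%Y-%m", tz = "UTC")
  months <- sort(unique(month))
  out <- data.frame(
    month = months,
    n_total = vapply(months, function(m) sum(month == m), integer(1)),
    n_positive = vapply(months, function(m)
      sum(positive[month == m]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$percent <- vapply(seq_len(nrow(out)), function(i)
    percent(out$n_positive[i], out$n_total[i]), numeric(1))
  class(out) <- c("monthly_trend", "data.frame")
  out
}

#' @export
print.monthly_trend <- function(x, ...) {
  cat("Monthly positive-classification trend\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Plot a monthly trend
#'
#' Simple base-graphics line chart of the monthly positive percentage.
#'
#' @param x a `monthly_trend`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.monthly_trend <- function(x, ...) {
  graphics::plot(seq_len(nrow(x)), x$percent, type = "b", xaxt = "n",
                 xlab = "month", ylab = "% positive", ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$month, las = 2,
                 cex.axis = 0.8)
  invisible(x)
}

#' Write a monthly trend as CSV
#'
#' @param trend a `monthly_trend`.
#' @param path output path.
#' @export
write_trend_csv <- function(trend, path) {
  utils::write.csv(as.data.frame(trend), path, row.names = FALSE)
  invisible(path)
}

#' Run the full classification pipeline
#'
#' Executes dedupe, search-term filtering, train/test split, featurization,
#' hyperparameter tuning and fitting for both tasks, pooled-CV evaluation
#' with feature-group ablation, classification of the test set, percentage
#' summaries and monthly trend tables. Per-stage counts are logged to
#' stderr; every artifact is stamped with the seed and a hash of the
#' configuration.
#'
#' @param tweets corpus data frame with gold labels (at least on the
#'   training portion after the split).
#' @param outdir output directory (created if needed).
#' @param svm an [svm_config()]; its seed drives all randomness.
#' @param train_fraction,train_size passed to [split_train_test()].
#' @param search_terms drug-name filter terms.
#' @param tasks tasks to train.
#' @param ablation run the leave-one-group-out ablation per task.
#' @param registry,sentiment lexicons.
#' @return invisibly, a list with `stats`, per-task `results` (each holding
#'   `model`, `tuning`, `metrics`, `ablation`), `classified` (test-set
#'   predictions), `trends`, and `paths` of written artifacts.
#' @export
run_pipeline <- function(tweets, outdir, svm = svm_config(),
                         train_fraction = 0.2, train_size = NULL,
                         search_terms = default_search_terms(),
                         tasks = c("nonmedical", "side_effects"),
                         ablation = TRUE,
                         registry = load_default_lexicons(),
                         sentiment = load_sentiment_lexicon()) {
  stage <- "setup"
  log_stage <- function(...) message("[", stage, "] ", ...)
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  n_total <- nrow(tweets)
  deduped <- run("dedupe", dedupe(tweets))
  log_stage(n_total, " tweets in, ", nrow(deduped), " after dedupe")
  filtered <- run("filter", filter_search_terms(deduped, search_terms))
  log_stage(nrow(filtered), " tweets match the search terms")
  parts <- run("split", split_train_test(filtered, train_fraction,
                                         svm$seed, train_size))
  log_stage("train ", nrow(parts$train), " / test ", nrow(parts$test))

  feats_train <- run("featurize", featurize_corpus(parts$train, registry,
                                                   sentiment))
  feats_test <- run("featurize", featurize_corpus(parts$test, registry,
                                                  sentiment))

  stats <- list(
    seed = svm$seed,
    n_total = n_total,
    n_after_dedupe = nrow(deduped),
    n_matching_terms = nrow(filtered),
    n_train = nrow(parts$train),
    n_test = nrow(parts$test),
    train_percent = percent(nrow(parts$train), nrow(filtered)),
    labels = list()
  )
  for (task in tasks) {
    col <- task_label_column(task)
    if (col %in% names(feats_train)) {
      k <- sum(feats_train[[col]], na.rm = TRUE)
      stats$labels[[task]] <- list(
        n_positive = k, percent = percent(k, nrow(feats_train)))
    }
  }

  results <- list()
  classified <- data.frame(tweet_id = feats_test$tweet_id,
                           created_at = feats_test$created_at,
                           stringsAsFactors = FALSE)
  trends <- list()
  for (task in tasks) {
    res <- run(paste0("train_", task),
               train_and_evaluate(feats_train, task, svm, registry))
    log_stage("cost ", res$model$cost, ", gamma ", res$model$gamma,
              ", pooled-CV F1 ",
              round_half_up(res$metrics$f1_positive, 3L))
    if (ablation) {
      res$ablation <- run(paste0("ablate_", task),
                          run_ablation(feats_train, task, svm, registry))
    }
    pred <- run(paste0("classify_", task), {
      X <- select_task_features(feats_test, task, registry)
      predict(res$model, X, lexicon_version = registry$version)
    })
    classified[[paste0("pred_", task)]] <- pred
    log_stage(sum(pred), " of ", nrow(feats_test),
              " test tweets positive (",
              percent(sum(pred), max(nrow(feats_test), 1L)), "%)")
    trends[[task]] <- run(paste0("trend_", task),
                          monthly_trend(feats_test, pred))
    results[[task]] <- res
  }

  stage <- "artifacts"
  cfg_json <- jsonlite::toJSON(unclass(svm), auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  stamp <- list(seed = svm$seed, config_hash = config_hash,
                lexicon_version = registry$version)

  paths$stats <- file.path(outdir, "corpus_stats.json")
  jsonlite::write_json(c(stamp, stats), paths$stats, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (task in tasks) {
    res <- results[[task]]
    m <- res$metrics
    paths[[paste0("metrics_", task)]] <-
      file.path(outdir, paste0("metrics_", task, ".json"))
    jsonlite::write_json(
      c(stamp, list(
        task = task, cost = res$model$cost, gamma = res$model$gamma,
        cv_f1_tuning = res$tuning$cv_f1,
        confusion = res$confusion[c("tp", "fp", "tn", "fn")],
        precision = m$precision, recall = m$recall, accuracy = m$accuracy,
        f1_positive = m$f1_positive, f1_negative = m$f1_negative)),
      paths[[paste0("metrics_", task)]], auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    paths[[paste0("model_", task)]] <-
      file.path(outdir, paste0("model_", task, ".rds"))
    save_classifier(res$model, paths[[paste0("model_", task)]])
    if (!is.null(res$ablation)) {
      paths[[paste0("ablation_", task)]] <-
        file.path(outdir, paste0("ablation_", task, ".csv"))
      write_ablation_report(
        res$ablation,
        csv_path = paths[[paste0("ablation_", task)]],
        json_path = file.path(outdir, paste0("ablation_", task, ".json")))
    }
    paths[[paste0("trend_", task)]] <-
      file.path(outdir, paste0("trend_", task, ".csv"))
    write_trend_csv(trends[[task]], paths[[paste0("trend_", task)]])
  }
  paths$classified <- file.path(outdir, "classified_test.csv")
  df <- classified
  df$created_at <- format(df$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, paths$classified, row.names = FALSE)

  invisible(list(stats = stats, results = results, classified = classified,
                 trends = trends, paths = paths, stamp = stamp))
}
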