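test_that("split_dataset follows the floor-then-remainder-to-train rule", {
  ids75 <- sprintf("r%02d", 1:75)
  plan <- split_dataset(ids75, seed = 1)
  expect_length(plan$train_ids, 53)
  expect_length(plan$val_ids, 11)
  expect_length(plan$test_ids, 11)
  expect_setequal(c(plan$train_ids, plan$val_ids, plan$test_ids), ids75)

  plan10 <- split_dataset(sprintf("r%d", 1:10), seed = 3)
  expect_equal(lengths(plan10[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 8L, val_ids = 1L, test_ids = 1L))

  expect_identical(split_dataset(ids75, seed = 9), split_dataset(ids75, seed = 9))
  expect_error(split_dataset(ids75, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_dataset(c("a", "b")), "at least 3")
})

test_that("kfold_indices partitions exactly with near-equal sizes", {
  f75 <- kfold_indices(75, 75, seed = 2)
  expect_length(f75, 75)
  expect_true(all(lengths(f75) == 1))

  f60 <- kfold_indices(75, 60, seed = 2)
  expect_equal(sum(lengths(f60) == 2), 15)
  expect_equal(sum(lengths(f60) == 1), 45)

  for (K in c(2, 7, 10)) {
    folds <- kfold_indices(23, K, seed = K)
    expect_setequal(unlist(folds), 1:23)
    expect_equal(sum(lengths(folds)), 23)
    expect_lte(diff(range(lengths(folds))), 1)
  }
  expect_error(kfold_indices(5, 6), "K must be")
})

test_that("confusion_and_metrics reproduces the published formulas", {
  # binary counts TP=3 TN=5 FP=1 FN=1 (positive class "p")
  y_true <- c(rep("p", 4), rep("n", 6))
  y_pred <- c(rep("p", 3), "n", rep("n", 5), "p")
  m <- confusion_and_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.8)
  p_row <- m$per_class[m$per_class$class == "p", ]
  expect_equal(p_row$precision, 0.75)
  expect_equal(p_row$recall, 0.75)
  expect_equal(p_row$f1, 0.75)
  expect_equal(sum(m$confusion), 10)
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy,
               tolerance = 1e-12)

  perfect <- confusion_and_metrics(y_true, y_true)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # 3-class macro F1 equals the hand-computed per-class average
  set.seed(12)
  yt <- sample(c("a", "b", "c"), 30, replace = TRUE)
  yp <- yt
  yp[1:8] <- sample(c("a", "b", "c"), 8, replace = TRUE)
  mm <- confusion_and_metrics(yt, yp)
  per_f1 <- vapply(c("a", "b", "c"), function(k) {
    tp <- sum(yt == k & yp == k)
    fp <- sum(yt != k & yp == k)
    fn <- sum(yt == k & yp != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, 0)
  expect_equal(mm$f1, mean(per_f1), tolerance = 1e-12)
  # micro identities for single-label multi-class
  expect_equal(mm$micro_precision, mm$accuracy, tolerance = 1e-12)
  expect_equal(mm$micro_recall, mm$accuracy, tolerance = 1e-12)

  expect_error(confusion_and_metrics(character(0), character(0)), "empty")
})

test_that("roc_auc handles separation, ties, and midranks", {
  s <- cbind(p = c(0.9, 0.8, 0.3, 0.2), n = c(0.1, 0.2, 0.7, 0.8))
  y <- c("p", "p", "n", "n")
  expect_equal(as.numeric(roc_auc(s, y)), 1.0)

  tied <- cbind(p = rep(0.4, 6), n = rep(0.4, 6))
  expect_equal(as.numeric(roc_auc(tied, c("p", "p", "p", "n", "n", "n"))),
               0.5)

  # class with no positives is excluded and flagged
  s3 <- cbind(a = runif(4), b = runif(4), c = runif(4))
  r <- roc_auc(s3, c("a", "a", "b", "b"))
  expect_match(attr(r, "flags"), "c")
  expect_length(attr(r, "per_class"), 2)
})

test_that("eer covers separable, overlapping and degenerate cases", {
  expect_equal(as.numeric(eer(c(0.9, 0.8), c(0.1, 0.2))), 0)
  expect_equal(as.numeric(eer(0.6, 0.6)), 0.5)

  set.seed(44)
  g <- runif(4000); i <- runif(4000)
  expect_lt(abs(as.numeric(eer(g, i)) - 0.5), 0.03)

  # bracketing: FAR and FRR at the crossing differ by <= 1/min(n_g, n_i)
  for (s in 1:10) {
    set.seed(s)
    g <- rnorm(40, 1); i <- rnorm(25, 0)
    e <- eer(g, i)
    expect_lte(abs(attr(e, "far") - attr(e, "frr")), 1 / 25 + 1e-12)
    expect_gte(as.numeric(e), 0)
    expect_lte(as.numeric(e), 1)
  }
  expect_error(eer(numeric(0), 1), "empty")
})

test_that("cross-validation produces per-fold reports and sane aggregates", {
  feats <- short_features()       # 3 subjects x 3 recordings
  cfg <- gcn_config(n_graph_layers = 2, channels = 8, dense_width = 16,
                    epochs = 30, seed = 4)
  cv <- run_cross_validation(feats, cfg, K = 3, seed = 11)
  expect_length(cv$folds, 3)
  expect_equal(sum(vapply(cv$folds, `[[`, 0, "n_test")), 9)
  accs <- vapply(cv$folds, `[[`, 0, "accuracy")
  expect_equal(unname(cv$mean_metrics["accuracy"]), mean(accs))

  # K = n is leave-one-out: every fold tests exactly one record
  cv_loo <- run_cross_validation(feats, gcn_config(n_graph_layers = 1,
                                                   channels = 4,
                                                   dense_width = 8,
                                                   epochs = 2, seed = 1),
                                 K = 9, seed = 5)
  expect_true(all(vapply(cv_loo$folds, `[[`, 0, "n_test") == 1))
  # singleton folds leave all classes in training except when a subject
  # has all its records in one fold -- here flags mark degenerate folds only
  expect_true(all(!vapply(cv_loo$folds, function(f)
    any(grepl("degenerate", f$flags)), TRUE)))
})

test_that("holdout evaluation returns a complete report", {
  feats <- short_features()
  rep <- evaluate_holdout(feats, gcn_config(n_graph_layers = 2,
                                            channels = 8, dense_width = 16,
                                            epochs = 30, seed = 2), seed = 6)
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(rep$eer >= 0 && rep$eer <= 1)
  expect_equal(sum(rep$confusion), rep$n_test)

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path, config_hash = "ffff")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-12)
  expect_identical(back$config, "ffff")

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(rep, cpath)
  cm <- read_mi_csv(cpath)
  expect_equal(sum(cm), rep$n_test)
})
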