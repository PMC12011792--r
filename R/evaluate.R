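#' 70/15/15 train/validation/test split
#'
#' Seeded shuffle followed by contiguous slicing; fold sizes are
#' `floor(n * ratio)` with the remainder assigned to the training set.
#'
#' @param record_ids Character vector of record ids (n >= 3).
#' @param ratios Length-3 ratios summing to 1 (default `c(0.70, 0.15,
#'   0.15)`).
#' @param seed Shuffle seed.
#' @return A `split_plan` with disjoint `train_ids`, `val_ids`, `test_ids`.
#' @export
split_dataset <- function(record_ids, ratios = c(0.70, 0.15, 0.15),
                          seed = 0) {
  n <- length(record_ids)
  if (n < 3) stop("need at least 3 records")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  rng <- local_rng(seed)
  on.exit(rng())
  perm <- sample(record_ids)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test         # remainder goes to train
  structure(list(train_ids = perm[seq_len(n_train)],
                 val_ids = perm[n_train + seq_len(n_val)],
                 test_ids = perm[n_train + n_val + seq_len(n_test)],
                 ratios = ratios, seed = seed),
            class = "split_plan")
}

#' K-fold test-index partition
#'
#' Seeded permutation of `1:n` cut into K folds whose sizes differ by at
#' most 1; `K = n` degenerates to leave-one-out.
#'
#' @param n Number of records.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Shuffle seed.
#' @return List of K disjoint integer index vectors covering `1:n`.
#' @export
kfold_indices <- function(n, K, seed = 0) {
  if (K < 2 || K > n) stop("K must be in [2, n]")
  rng <- local_rng(seed)
  on.exit(rng())
  perm <- sample.int(n)
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-K] + 1L)
  lapply(seq_len(K), function(k) sort(perm[starts[k]:ends[k]]))
}

#' Confusion matrix and classification metrics
#'
#' Multi-class one-vs-rest counts with macro-averaged precision, recall and
#' F1 (micro averages also reported; for single-label predictions
#' micro-precision = micro-recall = accuracy). A class with a zero
#' denominator contributes 0 and is flagged.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param levels Class levels (default: sorted union).
#' @return An `eval_metrics` list: `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1` (macro), `micro_*`, `per_class` table, `flags`.
#' @export
confusion_and_metrics <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(y_true, y_pred)))
  yt <- factor(y_true, levels = levels)
  yp <- factor(y_pred, levels = levels)
  confusion <- table(true = yt, predicted = yp)
  total <- length(yt)
  acc <- sum(diag(confusion)) / total
  K <- length(levels)
  per <- data.frame(class = levels, TP = 0, FP = 0, FN = 0, TN = 0,
                    precision = 0, recall = 0, f1 = 0,
                    stringsAsFactors = FALSE)
  flags <- character(0)
  for (k in seq_len(K)) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else {
      flags <- c(flags, paste0("zero-denominator precision: ", levels[k])); 0
    }
    rec <- if (tp + fn > 0) tp / (tp + fn) else {
      flags <- c(flags, paste0("zero-denominator recall: ", levels[k])); 0
    }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[k, 2:8] <- c(tp, fp, fn, tn, prec, rec, f1)
  }
  micro_tp <- sum(per$TP); micro_fp <- sum(per$FP); micro_fn <- sum(per$FN)
  micro_p <- micro_tp / (micro_tp + micro_fp)
  micro_r <- micro_tp / (micro_tp + micro_fn)
  structure(list(confusion = confusion, accuracy = acc,
                 precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), micro_precision = micro_p,
                 micro_recall = micro_r,
                 micro_f1 = 2 * micro_p * micro_r / (micro_p + micro_r),
                 per_class = per, flags = flags),
            class = "eval_metrics")
}

# midrank (Mann-Whitney) AUC for one binary split
binary_auc <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro one-vs-rest ROC-AUC
#'
#' Per-class AUC from the rank statistic (midranks under ties), averaged
#' over classes that have at least one positive and one negative.
#'
#' @param class_scores B x K score matrix (columns named by class).
#' @param y_true Length-B true labels.
#' @return Scalar AUC with attribute `per_class`; classes without positives
#'   are excluded and flagged in attribute `flags`.
#' @export
roc_auc <- function(class_scores, y_true) {
  s <- as.matrix(class_scores)
  levels <- colnames(s)
  if (is.null(levels)) stop("class_scores needs column names")
  aucs <- numeric(0); flags <- character(0)
  for (k in seq_along(levels)) {
    pos <- y_true == levels[k]
    if (!any(pos) || all(pos)) {
      flags <- c(flags, paste0("class without both outcomes: ", levels[k]))
      next
    }
    aucs[levels[k]] <- binary_auc(s[, k], pos)
  }
  out <- mean(aucs)
  attr(out, "per_class") <- aucs
  attr(out, "flags") <- flags
  out
}

#' Equal error rate of genuine vs impostor score distributions
#'
#' Sweeps thresholds over the pooled scores; `FAR(t)` is the share of
#' impostor scores `>= t`, `FRR(t)` the share of genuine scores `< t`. The
#' EER is taken at the FAR/FRR crossing, linearly interpolated between the
#' two bracketing thresholds.
#'
#' @param genuine_scores,impostor_scores Non-empty numeric vectors.
#' @return Scalar in `[0, 1]` with attributes `threshold`, `far`, `frr`.
#' @export
eer <- function(genuine_scores, impostor_scores) {
  g <- as.numeric(genuine_scores); i <- as.numeric(impostor_scores)
  if (!length(g) || !length(i)) stop("empty score list")
  ts <- sort(unique(c(g, i)))
  ts <- c(ts, ts[length(ts)] + 1)    # one threshold above everything
  far <- vapply(ts, function(t) mean(i >= t), 0)
  frr <- vapply(ts, function(t) mean(g < t), 0)
  d <- far - frr                      # decreasing from >=0 to -1
  j <- which(d <= 0)[1]
  if (is.na(j)) j <- length(ts)
  if (d[j] == 0 || j == 1) {
    val <- (far[j] + frr[j]) / 2
    thr <- ts[j]
  } else {
    alpha <- d[j - 1] / (d[j - 1] - d[j])
    val <- far[j - 1] + alpha * (far[j] - far[j - 1])
    thr <- ts[j - 1] + alpha * (ts[j] - ts[j - 1])
  }
  out <- val
  attr(out, "threshold") <- thr
  attr(out, "far") <- far[j]
  attr(out, "frr") <- frr[j]
  out
}

# Build an evaluation report from predictions on a test partition.
# Identification-to-verification score pooling: genuine = score assigned to
# the true class, impostor = scores assigned to every other class.
evaluation_report <- function(preds, levels, fold_id = 1L,
                              flags = character(0)) {
  y_true <- vapply(preds, `[[`, "", "true_label")
  y_pred <- vapply(preds, `[[`, "", "predicted_label")
  scores <- do.call(rbind, lapply(preds, `[[`, "class_scores"))
  colnames(scores) <- levels
  core <- confusion_and_metrics(y_true, y_pred, levels = levels)
  auc <- tryCatch(as.numeric(roc_auc(scores, y_true)), error = function(e)
    NA_real_)
  ti <- match(y_true, levels)
  genuine <- scores[cbind(seq_along(ti), ti)]
  impostor <- as.vector(scores)[-((ti - 1) * length(ti) + seq_along(ti))]
  e <- as.numeric(eer(genuine, impostor))
  structure(list(fold_id = fold_id, confusion = core$confusion,
                 accuracy = core$accuracy, precision = core$precision,
                 recall = core$recall, f1 = core$f1,
                 micro_precision = core$micro_precision,
                 micro_recall = core$micro_recall, auc = auc, eer = e,
                 per_class = core$per_class,
                 n_test = length(preds),
                 flags = c(flags, core$flags)),
            class = "evaluation_report")
}

#' Hold-out evaluation under the 70/15/15 protocol
#'
#' @param features_list Labelled cohort (`lead_features` list).
#' @param cfg A [gcn_config()].
#' @param seed Split seed.
#' @param ... Passed to [train_gcn()] (adjacency mode, tau, ...).
#' @return An `evaluation_report` for the test partition, with the trained
#'   model in attribute `model`.
#' @export
evaluate_holdout <- function(features_list, cfg = gcn_config(), seed = 0,
                             ...) {
  ids <- vapply(features_list, `[[`, "", "record_id")
  plan <- split_dataset(ids, seed = seed)
  train_set <- features_list[ids %in% plan$train_ids]
  test_set <- features_list[ids %in% plan$test_ids]
  model <- train_gcn(train_set, cfg, ...)
  preds <- lapply(test_set, predict_gcn, model = model)
  rep <- evaluation_report(preds, model$class_levels)
  attr(rep, "model") <- model
  attr(rep, "split") <- plan
  rep
}

#' K-fold (or leave-one-out) cross-validation of the classifier
#'
#' Each fold is held out once, the model retrained on the remaining folds.
#' A fold whose training partition lacks a class is flagged "degenerate
#' fold" rather than silently scored.
#'
#' @param features_list Labelled cohort.
#' @param cfg A [gcn_config()].
#' @param K Fold count; `K = length(features_list)` is leave-one-out.
#' @param seed Partition seed (also offsets each fold's training seed).
#' @param ... Passed to [train_gcn()].
#' @return A `cv_result`: list of per-fold `evaluation_report`s plus
#'   aggregate mean metrics.
#' @export
run_cross_validation <- function(features_list, cfg = gcn_config(), K = 10,
                                 seed = 0, ...) {
  n <- length(features_list)
  folds <- kfold_indices(n, K, seed = seed)
  all_labels <- sort(unique(vapply(features_list, `[[`, "", "subject_id")))
  reports <- vector("list", K)
  for (k in seq_len(K)) {
    test_idx <- folds[[k]]
    train_set <- features_list[-test_idx]
    flags <- character(0)
    train_labels <- unique(vapply(train_set, `[[`, "", "subject_id"))
    if (!setequal(train_labels, all_labels))
      flags <- "degenerate fold: training partition lacks a class"
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + k
    model <- train_gcn(train_set, fold_cfg, ...)
    preds <- lapply(features_list[test_idx], predict_gcn, model = model)
    reports[[k]] <- evaluation_report(preds, all_labels, fold_id = k,
                                      flags = flags)
  }
  agg <- sapply(c("accuracy", "precision", "recall", "f1", "auc", "eer"),
                function(m) mean(vapply(reports, `[[`, 0, m), na.rm = TRUE))
  structure(list(folds = reports, mean_metrics = agg, K = K, seed = seed),
            class = "cv_result")
}

#' Write an evaluation report as JSON (plus confusion CSV)
#' @param report An `evaluation_report` or `cv_result`.
#' @param path Output JSON path.
#' @param config_hash Optional provenance string.
#' @export
write_report_json <- function(report, path, config_hash = NULL) {
  to_list <- function(r) list(
    fold_id = r$fold_id, accuracy = r$accuracy, precision = r$precision,
    recall = r$recall, f1 = r$f1, auc = r$auc, eer = r$eer,
    n_test = r$n_test, flags = r$flags,
    confusion = as.data.frame.matrix(unclass(r$confusion)))
  obj <- if (inherits(report, "cv_result"))
    list(kind = "cv", K = report$K, seed = report$seed,
         mean_metrics = as.list(report$mean_metrics),
         folds = lapply(report$folds, to_list))
  else c(list(kind = "holdout"), to_list(report))
  if (!is.null(config_hash)) obj$config <- config_hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a confusion matrix as CSV
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @export
write_confusion_csv <- function(report, path) {
  m <- unclass(report$confusion)
  write_matrix_csv(m, path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report fold=%s n=%d acc=%.4f P=%.4f ",
                     "R=%.4f F1=%.4f AUC=%.4f EER=%.4f>\n"),
              x$fold_id, x$n_test, x$accuracy, x$precision, x$recall,
              x$f1, x$auc, x$eer))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result K=%d mean accuracy=%.4f>\n", x$K,
              x$mean_metrics["accuracy"]))
  invisible(x)
}
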