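test_that("activations match their closed forms", {
  expect_equal(relu(3), 3)
  expect_equal(relu(-2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))

  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 1 / (1 + exp(-1)))
  x <- c(-700, -3, 0.2, 5, 700)
  expect_equal(sigmoid(-x), 1 - sigmoid(x), tolerance = 1e-12)
  expect_true(all(sigmoid(c(-1e3, 1e3)) >= 0 & sigmoid(c(-1e3, 1e3)) <= 1))
})

test_that("gcn_layer equals the brute-force composition", {
  h <- matrix(1:6, 3)
  expect_equal(gcn_layer(h, diag(3), diag(2), identity), h)
  expect_equal(gcn_layer(h + 10, diag(3), -diag(2)), matrix(0, 3, 2))

  set.seed(21)
  for (i in 1:25) {
    a <- matrix(abs(rnorm(25)), 5); a <- a + t(a)
    ah <- normalize_adjacency(a)
    hin <- matrix(rnorm(15), 5)
    w <- matrix(rnorm(12), 3, 4)
    got <- gcn_layer(hin, ah, w)
    oracle <- matmul_oracle(matmul_oracle(ah$values, hin), w)
    oracle[oracle < 0] <- 0
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  expect_error(gcn_layer(matrix(1, 3, 2), diag(3), matrix(1, 3, 2)),
               "mismatch")
})

test_that("losses match closed forms and hand oracles", {
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-11)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2))
  y <- c(1, 0, 1); p <- c(0.9, 0.2, 0.8)
  expect_equal(bce_loss(y, p),
               -mean(c(log(0.9), log(0.8), log(0.8))), tolerance = 1e-12)
  expect_error(bce_loss(c(1, 0), 0.5), "mismatch")

  oh <- diag(3)
  expect_equal(categorical_ce_loss(oh, oh * (1 - 2e-12) + 1e-12), 0,
               tolerance = 1e-9)
  unif <- matrix(1 / 4, 2, 4)
  expect_equal(categorical_ce_loss(cbind(1, 0, 0, 0)[c(1, 1), ], unif),
               log(4))
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.25, 0.25, 0.5))
  expect_equal(categorical_ce_loss(oh, probs),
               -mean(log(c(0.7, 0.6, 0.5))), tolerance = 1e-12)
  expect_error(categorical_ce_loss(oh, oh * 0.5), "sum to 1")
})

test_that("forward pass is deterministic, normalized, and dropout-clean", {
  feats <- short_features()
  cfg <- gcn_config(n_graph_layers = 2, channels = 8, dense_width = 16,
                    epochs = 5, seed = 3)
  model <- train_gcn(feats, cfg)
  s1 <- gcn_forward(model, feats[[1]])
  s2 <- gcn_forward(model, feats[[1]])
  expect_identical(s1, s2)
  expect_equal(sum(s1), 1, tolerance = 1e-9)
  expect_true(all(s1 >= 0 & s1 <= 1))

  cfg0 <- gcn_config(n_graph_layers = 2, channels = 8, dense_width = 16,
                     dropout_p = 0, epochs = 5, seed = 3)
  m0 <- train_gcn(feats, cfg0)
  expect_equal(gcn_forward(m0, feats[[2]], train_mode = TRUE, seed = 1),
               gcn_forward(m0, feats[[2]]), tolerance = 1e-9)
})

test_that("forward pass equals an all-loop brute-force implementation", {
  feats <- short_features()
  cfg <- gcn_config(n_graph_layers = 2, channels = 4, dense_layers = 2,
                    dense_width = 5, epochs = 2, seed = 11)
  model <- train_gcn(feats, cfg)
  f <- feats[[1]]
  got <- gcn_forward(model, f)

  # loop-only reimplementation of the published layer composition
  p <- model$params
  ah <- ecgid::lead_graph(f, tau = model$tau, cfg = model$disc_cfg)$values
  relu_m <- function(m) { m[m < 0] <- 0; m }
  h <- relu_m(sweep(matmul_oracle(f$features, p$W0), 2, p$b0, `+`))
  for (l in seq_along(p$Wg))
    h <- relu_m(matmul_oracle(matmul_oracle(ah, h), p$Wg[[l]]))
  flat <- numeric(0)
  for (ch in seq_len(ncol(h))) flat <- c(flat, h[, ch])
  d <- flat
  for (l in seq_along(p$Wd))
    d <- relu_m(matrix(d, 1) %*% p$Wd[[l]] + p$bd[[l]])
  logits <- matrix(d, 1) %*% p$Wo + p$bo
  probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
  expect_equal(unname(got), as.vector(probs), tolerance = 1e-9)
})

test_that("training learns, reproduces bit-for-bit, and honors lr = 0", {
  feats <- short_features()
  cfg <- gcn_config(n_graph_layers = 2, channels = 16, dense_width = 32,
                    epochs = 40, seed = 5)
  m1 <- train_gcn(feats, cfg)
  m2 <- train_gcn(feats, cfg)
  expect_identical(m1$params, m2$params)

  preds <- vapply(feats, function(f) predict_gcn(m1, f)$predicted_label, "")
  truth <- vapply(feats, `[[`, "", "subject_id")
  expect_gte(mean(preds == truth), 0.95)
  # epoch-averaged loss decreases over the run
  lh <- m1$loss_history
  expect_lt(mean(lh[31:40]), mean(lh[1:10]))

  frozen <- train_gcn(feats, gcn_config(n_graph_layers = 2, channels = 16,
                                        dense_width = 32, epochs = 3,
                                        learning_rate = 0, seed = 5))
  init <- train_gcn(feats, gcn_config(n_graph_layers = 2, channels = 16,
                                      dense_width = 32, epochs = 0,
                                      learning_rate = 0, seed = 5))
  expect_equal(frozen$params, init$params, tolerance = 1e-15)

  one_class <- feats[1:2]
  one_class <- lapply(one_class, function(f) { f$subject_id <- "s"; f })
  expect_error(train_gcn(one_class, cfg), "2 classes")
})

test_that("verify mode trains with sigmoid + BCE and thresholds at 0.5", {
  feats <- short_features()
  cfg <- gcn_config(n_graph_layers = 2, channels = 16, dense_width = 32,
                    epochs = 40, seed = 5, output_mode = "sigmoid_verify")
  m <- train_gcn(feats, cfg)
  res <- predict_gcn(m, feats[[1]])
  expect_true(all(res$class_scores >= 0 & res$class_scores <= 1))
  expect_identical(unname(res$accepted), unname(res$class_scores >= 0.5))
})

test_that("argmax prediction breaks ties toward the lowest class index", {
  feats <- short_features()
  m <- train_gcn(feats, gcn_config(n_graph_layers = 1, channels = 4,
                                   dense_width = 4, epochs = 1, seed = 2))
  # which.max tie-break is position of first maximum
  scores <- c(a = 0.5, b = 0.5)
  expect_identical(names(scores)[which.max(scores)], "a")
  res <- predict_gcn(m, feats[[3]])
  expect_identical(res$predicted_label,
                   m$class_levels[which.max(res$class_scores)])
  um <- m; um$trained <- FALSE
  expect_error(predict_gcn(um, feats[[1]]), "not trained")
})

test_that("cohort-average adjacency mode works end to end", {
  feats <- short_features()
  g <- cohort_graph(feats)
  expect_equal(dim(g$values), c(12, 12))
  m <- train_gcn(feats, gcn_config(n_graph_layers = 2, channels = 8,
                                   dense_width = 16, epochs = 10, seed = 1),
                 adjacency_mode = "cohort")
  expect_identical(m$adjacency_mode, "cohort")
  expect_length(gcn_forward(m, feats[[1]]), 3)
})

test_that("checkpoints restore bit-identical inference", {
  feats <- short_features()
  cfg <- gcn_config(n_graph_layers = 2, channels = 8, dense_width = 16,
                    epochs = 8, seed = 9)
  m <- train_gcn(feats, cfg)
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  save_gcn(m, prefix)
  m2 <- load_gcn(prefix)
  expect_identical(gcn_forward(m, feats[[1]]), gcn_forward(m2, feats[[1]]))
  expect_identical(m$class_levels, m2$class_levels)
})
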