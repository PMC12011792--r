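#' GCN classifier configuration
#'
#' @param n_graph_layers Number of graph-convolution blocks. The named
#'   variants use 5, 10 or 15.
#' @param channels Channels per node after the input projection (64).
#' @param dense_layers Depth of the dense head after flattening (the tuned
#'   13-layer head is configurable; 2 is the stable desk-scale default).
#' @param dense_width Neurons per dense layer (64).
#' @param dropout_p Dropout probability applied after the graph blocks in
#'   training mode only (tuned value 0.2).
#' @param output_mode `"softmax_identify"` (1-of-K identification,
#'   categorical cross-entropy) or `"sigmoid_verify"` (per-class sigmoid,
#'   binary cross-entropy).
#' @param learning_rate Adam step size (0.001).
#' @param epochs Training epochs (600).
#' @param batch_size Mini-batch size; `NULL` = full batch.
#' @param seed Seed controlling initialization and dropout; fixed seed on a
#'   single thread makes training bit-reproducible.
#' @return An object of class `gcn_config`.
#' @export
gcn_config <- function(n_graph_layers = 5, channels = 64, dense_layers = 2,
                       dense_width = 64, dropout_p = 0.2,
                       output_mode = c("softmax_identify", "sigmoid_verify"),
                       learning_rate = 0.001, epochs = 600,
                       batch_size = NULL, seed = 0) {
  output_mode <- match.arg(output_mode)
  if (n_graph_layers < 1) stop("n_graph_layers must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(n_graph_layers = as.integer(n_graph_layers),
                 channels = as.integer(channels),
                 dense_layers = as.integer(dense_layers),
                 dense_width = as.integer(dense_width),
                 dropout_p = as.numeric(dropout_p),
                 output_mode = output_mode,
                 learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.numeric(seed)),
            class = "gcn_config")
}

#' Rectified linear unit: max(0, x)
#' @param x Numeric scalar/array.
#' @return Same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable logistic sigmoid 1/(1 + exp(-x))
#' @param x Numeric scalar/array.
#' @return Same shape, values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' One graph-convolution layer: activation(A_hat H W)
#'
#' `adjacency` must already be symmetrically normalized (normalization is
#' applied exactly once, at graph construction).
#'
#' @param node_features N x C_in matrix H.
#' @param adjacency A `norm_adjacency` or plain N x N matrix.
#' @param weights C_in x C_out weight matrix W.
#' @param activation Elementwise function (default [relu()]).
#' @return N x C_out matrix.
#' @export
gcn_layer <- function(node_features, adjacency, weights, activation = relu) {
  a <- if (inherits(adjacency, "norm_adjacency")) adjacency$values
       else as.matrix(adjacency)
  h <- as.matrix(node_features)
  if (ncol(a) != nrow(h) || nrow(weights) != ncol(h))
    stop("shape mismatch in gcn_layer")
  activation(a %*% h %*% weights)
}

# fan-in-scaled uniform init, consuming the active RNG stream
init_mat <- function(nr, nc) {
  lim <- 1 / sqrt(nr)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_gcn_params <- function(input_dim, n_nodes, n_classes, cfg) {
  C <- cfg$channels
  p <- list(W0 = init_mat(input_dim, C), b0 = numeric(C))
  p$Wg <- lapply(seq_len(cfg$n_graph_layers), function(l) init_mat(C, C))
  widths <- c(n_nodes * C, rep(cfg$dense_width, cfg$dense_layers))
  p$Wd <- lapply(seq_len(cfg$dense_layers),
                 function(l) init_mat(widths[l], widths[l + 1]))
  p$bd <- lapply(seq_len(cfg$dense_layers),
                 function(l) numeric(widths[l + 1]))
  p$Wo <- init_mat(cfg$dense_width, n_classes)
  p$bo <- numeric(n_classes)
  p
}

# flatten (B*N) x C node-major activations into B x (N*C) sample rows
flatten_nodes <- function(h, n_nodes, batch) {
  matrix(aperm(array(h, c(n_nodes, batch, ncol(h))), c(2, 1, 3)),
         nrow = batch)
}
unflatten_nodes <- function(fl, n_nodes, batch, channels) {
  matrix(aperm(array(fl, c(batch, n_nodes, channels)), c(2, 1, 3)),
         nrow = batch * n_nodes)
}

# Batched forward pass. x_all: (B*N) x F node-major stack; a_block: sparse
# block-diagonal normalized adjacency. Returns intermediates for backprop.
gcn_forward_pass <- function(params, x_all, a_block, cfg, n_nodes, batch,
                             train_mode = FALSE, keep = TRUE) {
  Z0 <- sweep(x_all %*% params$W0, 2, params$b0, `+`)
  H <- relu(Z0)
  Hs <- list(H)
  for (l in seq_along(params$Wg)) {
    Z <- as.matrix(a_block %*% (H %*% params$Wg[[l]]))
    H <- relu(Z)
    Hs[[l + 1]] <- H
  }
  mask <- NULL
  if (train_mode && cfg$dropout_p > 0) {
    mask <- matrix(runif(length(H)) >= cfg$dropout_p, nrow(H), ncol(H))
    H <- H * mask / (1 - cfg$dropout_p)
  }
  Fl <- flatten_nodes(H, n_nodes, batch)
  Ds <- list(Fl)
  for (l in seq_along(params$Wd)) {
    Zd <- sweep(Ds[[l]] %*% params$Wd[[l]], 2, params$bd[[l]], `+`)
    Ds[[l + 1]] <- relu(Zd)
  }
  logits <- sweep(Ds[[length(Ds)]] %*% params$Wo, 2, params$bo, `+`)
  scores <- if (cfg$output_mode == "softmax_identify") {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  } else sigmoid(logits)
  out <- list(scores = scores, logits = logits)
  if (keep) {
    out$Z0 <- Z0; out$Hs <- Hs; out$mask <- mask; out$Ds <- Ds
  }
  out
}

# Gradients of the mean cross-entropy loss wrt every parameter. For both
# output modes d logits = (scores - Y) / B (softmax+CE and sigmoid+BCE share
# this form; BCE is additionally averaged over classes).
gcn_backward_pass <- function(params, fw, x_all, a_block, y_onehot, cfg,
                              n_nodes, batch) {
  B <- batch
  dlog <- (fw$scores - y_onehot) / B
  if (cfg$output_mode == "sigmoid_verify") dlog <- dlog / ncol(y_onehot)
  g <- list()
  Dlast <- fw$Ds[[length(fw$Ds)]]
  g$Wo <- crossprod(Dlast, dlog)
  g$bo <- colSums(dlog)
  dD <- dlog %*% t(params$Wo)
  g$Wd <- vector("list", length(params$Wd))
  g$bd <- vector("list", length(params$Wd))
  for (l in rev(seq_along(params$Wd))) {
    dZd <- dD * (fw$Ds[[l + 1]] > 0)
    g$Wd[[l]] <- crossprod(fw$Ds[[l]], dZd)
    g$bd[[l]] <- colSums(dZd)
    dD <- dZd %*% t(params$Wd[[l]])
  }
  dH <- unflatten_nodes(dD, n_nodes, B, cfg$channels)
  if (!is.null(fw$mask)) dH <- dH * fw$mask / (1 - cfg$dropout_p)
  g$Wg <- vector("list", length(params$Wg))
  for (l in rev(seq_along(params$Wg))) {
    Hin <- fw$Hs[[l]]
    dZ <- dH * (fw$Hs[[l + 1]] > 0)
    M <- as.matrix(a_block %*% Hin)
    g$Wg[[l]] <- crossprod(M, dZ)
    dM <- as.matrix(a_block %*% dZ)          # a_block symmetric
    dH <- dM %*% t(params$Wg[[l]])
  }
  dZ0 <- dH * (fw$Z0 > 0)
  g$W0 <- crossprod(x_all, dZ0)
  g$b0 <- colSums(dZ0)
  g
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with probabilities clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities, same length/shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p)) stop("length mismatch")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Categorical cross-entropy loss
#'
#' @param one_hot_labels B x K 0/1 matrix with one 1 per row.
#' @param class_probabilities B x K matrix; rows must sum to 1 (within 1e-6).
#' @return Mean of `-log p[true class]`, clipped as in [bce_loss()].
#' @export
categorical_ce_loss <- function(one_hot_labels, class_probabilities) {
  y <- as.matrix(one_hot_labels)
  p <- as.matrix(class_probabilities)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  pt <- rowSums(y * p)
  pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  -mean(log(pt))
}

model_adjacency <- function(model, features) {
  if (model$adjacency_mode == "cohort") model$cohort_adj
  else lead_graph(features, tau = model$tau, cfg = model$disc_cfg)
}

build_batch <- function(features_list, model) {
  N <- 12L
  B <- length(features_list)
  x_all <- do.call(rbind, lapply(features_list, `[[`, "features"))
  adjs <- lapply(features_list, function(f) model_adjacency(model, f)$values)
  list(x_all = x_all, adjs = adjs, a_block = Matrix::bdiag(adjs),
       n_nodes = N, batch = B)
}

#' Train the MI-graph GCN classifier
#'
#' Full pipeline classifier training: per-recording (or cohort-average)
#' normalized MI lead graphs, input projection, stacked graph convolutions,
#' dense head, softmax/sigmoid output, Adam optimizer (beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8), full-batch by default. With a fixed seed on a
#' single thread the run is bit-reproducible.
#'
#' @param features_list List of `lead_features` (the training cohort).
#' @param cfg A [gcn_config()].
#' @param labels Class labels per element; default the `subject_id`s.
#' @param adjacency_mode `"per_record"` (each recording contributes its own
#'   12 x 12 graph) or `"cohort"` (one averaged graph for all).
#' @param tau Adjacency threshold.
#' @param disc_cfg Discretization config for the MI estimator.
#' @return A trained `gcn_model` with a recorded `loss_history`.
#' @export
train_gcn <- function(features_list, cfg = gcn_config(), labels = NULL,
                      adjacency_mode = c("per_record", "cohort"), tau = 0,
                      disc_cfg = discretization_config()) {
  adjacency_mode <- match.arg(adjacency_mode)
  if (is.null(labels))
    labels <- vapply(features_list, `[[`, "", "subject_id")
  lv <- sort(unique(labels))
  if (length(lv) < 2) stop("training needs at least 2 classes")
  y_idx <- match(labels, lv)
  K <- length(lv)
  input_dim <- ncol(features_list[[1]]$features)

  model <- structure(list(cfg = cfg, class_levels = lv,
                          lead_names = features_list[[1]]$lead_names,
                          input_dim = input_dim,
                          adjacency_mode = adjacency_mode, tau = tau,
                          disc_cfg = disc_cfg, cohort_adj = NULL,
                          trained = FALSE),
                     class = "gcn_model")
  if (adjacency_mode == "cohort")
    model$cohort_adj <- cohort_graph(features_list, tau = tau, cfg = disc_cfg)

  rng <- local_rng(cfg$seed)
  on.exit(rng())
  params <- init_gcn_params(input_dim, 12L, K, cfg)
  bt <- build_batch(features_list, model)
  y_onehot <- matrix(0, bt$batch, K)
  y_onehot[cbind(seq_len(bt$batch), y_idx)] <- 1

  # Adam state
  zeros_like <- function(p) rapply(p, function(z) z * 0, how = "replace")
  m <- zeros_like(params); v <- zeros_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  step <- 0L
  loss_hist <- numeric(cfg$epochs)

  bs <- if (is.null(cfg$batch_size)) bt$batch else min(cfg$batch_size,
                                                       bt$batch)
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (bs < bt$batch) sample.int(bt$batch) else seq_len(bt$batch)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, bt$batch, by = bs)) {
      idx <- ord[start:min(start + bs - 1, bt$batch)]
      if (length(idx) == bt$batch) {
        xb <- bt$x_all; ab <- bt$a_block; yb <- y_onehot
      } else {
        rows <- as.vector(outer(seq_len(12), (idx - 1) * 12, `+`))
        xb <- bt$x_all[rows, , drop = FALSE]
        ab <- Matrix::bdiag(bt$adjs[idx])
        yb <- y_onehot[idx, , drop = FALSE]
      }
      fw <- gcn_forward_pass(params, xb, ab, cfg, 12L, length(idx),
                             train_mode = TRUE)
      loss <- if (cfg$output_mode == "softmax_identify")
        categorical_ce_loss(yb, fw$scores)
      else bce_loss(as.vector(yb), as.vector(fw$scores))
      g <- gcn_backward_pass(params, fw, xb, ab, yb, cfg, 12L, length(idx))
      step <- step + 1L
      # Adam update over the nested parameter list
      upd <- function(p, gr, mm, vv) {
        mm2 <- b1 * mm + (1 - b1) * gr
        vv2 <- b2 * vv + (1 - b2) * gr^2
        mh <- mm2 / (1 - b1^step)
        vh <- vv2 / (1 - b2^step)
        list(p = p - lr * mh / (sqrt(vh) + eps), m = mm2, v = vv2)
      }
      walk <- function(p, gr, mm, vv) {
        if (is.list(p)) {
          out <- list(p = p, m = mm, v = vv)
          keys <- if (is.null(names(p))) seq_along(p) else names(p)
          for (nm in keys) {
            r <- walk(p[[nm]], gr[[nm]], mm[[nm]], vv[[nm]])
            out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
          }
          out
        } else upd(p, gr, mm, vv)
      }
      r <- walk(params, g, m, v)
      params <- r$p; m <- r$m; v <- r$v
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    loss_hist[ep] <- ep_loss / nb
  }
  model$params <- params
  model$loss_history <- loss_hist
  model$trained <- TRUE
  model
}

#' Forward pass for one recording
#'
#' @param model A trained `gcn_model` (or one with parameters attached).
#' @param features A `lead_features` object.
#' @param train_mode Apply dropout (seeded) as in training.
#' @param seed Dropout seed when `train_mode = TRUE`.
#' @return Numeric score vector over classes (softmax probabilities summing
#'   to 1, or per-class sigmoid scores).
#' @export
gcn_forward <- function(model, features, train_mode = FALSE, seed = 0) {
  if (is.null(model$params)) stop("model has no parameters (untrained?)")
  adj <- model_adjacency(model, features)
  if (is.null(adj)) stop("no adjacency attached to model")
  restore <- NULL
  if (train_mode) {
    restore <- local_rng(seed)
    on.exit(restore())
  }
  fw <- gcn_forward_pass(model$params, features$features, adj$values,
                         model$cfg, 12L, 1L, train_mode = train_mode,
                         keep = FALSE)
  scores <- as.vector(fw$scores)
  names(scores) <- model$class_levels
  scores
}

#' Predict the identity (or verify) for one recording
#'
#' Identify mode: argmax of class scores, ties broken toward the lowest
#' class index. Verify mode: per-class accept at score >= 0.5.
#'
#' @param model A trained `gcn_model`.
#' @param features A `lead_features`.
#' @return A `prediction_result` with `record_id`, `true_label`,
#'   `predicted_label`, `class_scores` (and `accepted` in verify mode).
#' @export
predict_gcn <- function(model, features) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  scores <- gcn_forward(model, features)
  pred <- model$class_levels[which.max(scores)]
  res <- structure(list(record_id = features$record_id,
                        true_label = features$subject_id,
                        predicted_label = pred, class_scores = scores),
                   class = "prediction_result")
  if (model$cfg$output_mode == "sigmoid_verify")
    res$accepted <- scores >= 0.5
  res
}

#' @export
predict.gcn_model <- function(object, features, ...) {
  if (inherits(features, "lead_features")) predict_gcn(object, features)
  else lapply(features, predict_gcn, model = object)
}

## ---- checkpoint serialization: JSON header + flat double blob ----

flatten_params <- function(p) {
  unlist(rapply(p, as.numeric, how = "unlist"), use.names = FALSE)
}

param_shapes <- function(input_dim, n_nodes, n_classes, cfg) {
  C <- cfg$channels
  widths <- c(n_nodes * C, rep(cfg$dense_width, cfg$dense_layers))
  list(W0 = c(input_dim, C), b0 = C,
       Wg = lapply(seq_len(cfg$n_graph_layers), function(l) c(C, C)),
       Wd = lapply(seq_len(cfg$dense_layers),
                   function(l) c(widths[l], widths[l + 1])),
       bd = lapply(seq_len(cfg$dense_layers), function(l) widths[l + 1]),
       Wo = c(cfg$dense_width, n_classes), bo = n_classes)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is `<prefix>.json` (config, class map, lead order,
#' adjacency) plus `<prefix>.bin`, a flat little-endian double array of all
#' parameters in a documented order (W0, b0, Wg..., Wd..., bd..., Wo, bo).
#' Loading restores bit-identical inference.
#'
#' @param model A trained `gcn_model`.
#' @param path_prefix Output path without extension.
#' @export
save_gcn <- function(model, path_prefix) {
  hdr <- list(cfg = strip_class(unclass(model$cfg)),
              class_levels = model$class_levels,
              lead_names = model$lead_names,
              input_dim = model$input_dim,
              adjacency_mode = model$adjacency_mode, tau = model$tau,
              disc_cfg = strip_class(unclass(model$disc_cfg)),
              cohort_adj = if (!is.null(model$cohort_adj))
                list(values = as.vector(model$cohort_adj$values),
                     degrees = model$cohort_adj$degrees),
              loss_history = model$loss_history)
  jsonlite::write_json(hdr, paste0(path_prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  con <- file(paste0(path_prefix, ".bin"), "wb")
  writeBin(flatten_params(model$params), con, size = 8, endian = "little")
  close(con)
  invisible(path_prefix)
}

#' @rdname save_gcn
#' @param path_prefix Checkpoint path prefix to read.
#' @return `load_gcn` returns the restored `gcn_model`.
#' @export
load_gcn <- function(path_prefix) {
  hdr <- jsonlite::read_json(paste0(path_prefix, ".json"),
                             simplifyVector = TRUE)
  cfg <- do.call(gcn_config, hdr$cfg[setdiff(names(hdr$cfg), "batch_size")])
  if (!is.null(hdr$cfg$batch_size)) cfg$batch_size <- hdr$cfg$batch_size
  K <- length(hdr$class_levels)
  shapes <- param_shapes(hdr$input_dim, 12L, K, cfg)
  n_par <- sum(unlist(rapply(shapes, prod, how = "unlist")))
  con <- file(paste0(path_prefix, ".bin"), "rb")
  flat <- readBin(con, "double", n = n_par, size = 8, endian = "little")
  close(con)
  pos <- 0L
  take <- function(shape) {
    n <- prod(shape)
    v <- flat[(pos + 1):(pos + n)]
    pos <<- pos + n
    if (length(shape) == 2) matrix(v, shape[1], shape[2]) else v
  }
  params <- list(W0 = take(shapes$W0), b0 = take(shapes$b0))
  params$Wg <- lapply(shapes$Wg, take)
  params$Wd <- lapply(shapes$Wd, take)
  params$bd <- lapply(shapes$bd, take)
  params$Wo <- take(shapes$Wo)
  params$bo <- take(shapes$bo)
  cohort_adj <- NULL
  if (!is.null(hdr$cohort_adj) && length(hdr$cohort_adj)) {
    n <- length(hdr$cohort_adj$degrees)
    cohort_adj <- structure(
      list(values = matrix(hdr$cohort_adj$values, n, n),
           degrees = hdr$cohort_adj$degrees),
      class = "norm_adjacency")
  }
  structure(list(cfg = cfg, class_levels = hdr$class_levels,
                 lead_names = hdr$lead_names, input_dim = hdr$input_dim,
                 adjacency_mode = hdr$adjacency_mode, tau = hdr$tau,
                 disc_cfg = discretization_config(hdr$disc_cfg$n_bins,
                                                  hdr$disc_cfg$strategy),
                 cohort_adj = cohort_adj, params = params,
                 loss_history = hdr$loss_history, trained = TRUE),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf(
    "<gcn_model %s: %d graph layers x %d ch, %d dense, %d classes%s>\n",
    x$cfg$output_mode, x$cfg$n_graph_layers, x$cfg$channels,
    x$cfg$dense_layers, length(x$class_levels),
    if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}
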