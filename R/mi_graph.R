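#' Discretization configuration for entropy estimation
#'
#' The entropy, conditional entropy and mutual information estimators work on
#' an empirical histogram of discretized lead values; this config fixes the
#' binning.
#'
#' @param n_bins Number of bins (>= 2). Default 16.
#' @param strategy `"equal_width"` bins span `[min, max]`; `"equal_frequency"`
#'   bins hold (near-)equal counts.
#' @return An object of class `discretization_config`. Logarithms are always
#'   base 2 (bits).
#' @export
discretization_config <- function(n_bins = 16,
                                  strategy = c("equal_width",
                                               "equal_frequency")) {
  strategy <- match.arg(strategy)
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins), strategy = strategy,
                 log_base = 2),
            class = "discretization_config")
}

#' Discretize a series into integer symbols
#'
#' @param series Numeric vector.
#' @param cfg A [discretization_config()].
#' @return Integer symbols in `[0, n_bins)`. Equal-width bins span
#'   `[min, max]` with the maximum assigned to the last bin; a constant series
#'   maps to all-zero symbols (entropy 0).
#' @export
discretize <- function(series, cfg = discretization_config()) {
  x <- as.numeric(series)
  k <- cfg$n_bins
  if (cfg$strategy == "equal_width") {
    rng <- range(x)
    if (rng[1] == rng[2]) return(integer(length(x)))
    sym <- floor((x - rng[1]) / (rng[2] - rng[1]) * k)
    sym[sym == k] <- k - 1L
    as.integer(sym)
  } else {
    if (length(x) < k) stop("equal_frequency needs length >= n_bins")
    # rank-based equal-count binning (ties keep first-come order)
    r <- rank(x, ties.method = "first") - 1
    as.integer(floor(r * k / length(x)))
  }
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Shannon entropy of a symbol sequence (bits)
#' @param syms Integer symbols.
#' @return Entropy in bits; 0 log 0 is taken as 0.
#' @export
symbol_entropy <- function(syms) {
  entropy_from_counts(table(syms))
}

joint_counts <- function(x_syms, y_syms) {
  if (length(x_syms) != length(y_syms)) stop("length mismatch")
  nx <- max(x_syms) + 1L
  tabulate(as.integer(x_syms) + as.integer(y_syms) * nx + 1L)
}

#' Joint entropy H[X, Y] (bits)
#'
#' Empirical joint-histogram estimate of the uncertainty of the pair.
#'
#' @param x_syms,y_syms Equal-length integer symbol sequences.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(x_syms, y_syms) {
  entropy_from_counts(joint_counts(x_syms, y_syms))
}

#' Conditional entropy H[X | Y] (bits)
#'
#' Remaining uncertainty in X once Y is known, via the chain rule
#' `H[X|Y] = H[X,Y] - H[Y]` (identical within 1e-12 to the direct
#' sum over `-p(x,y) log2 p(x|y)`).
#'
#' @inheritParams joint_entropy
#' @return Conditional entropy in bits (>= 0 up to rounding).
#' @export
conditional_entropy <- function(x_syms, y_syms) {
  joint_entropy(x_syms, y_syms) - symbol_entropy(y_syms)
}

#' Mutual information between two series (bits)
#'
#' Discretizes both series and evaluates `I(X;Y) = H[X] + H[Y] - H[X,Y]` on
#' the empirical histograms. Captures linear and non-linear dependence;
#' symmetric and non-negative (within 1e-12 rounding).
#'
#' @param x,y Equal-length numeric vectors.
#' @param cfg A [discretization_config()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, cfg = discretization_config()) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 samples")
  xs <- discretize(x, cfg)
  ys <- discretize(y, cfg)
  symbol_entropy(xs) + symbol_entropy(ys) - joint_entropy(xs, ys)
}

#' Inter-lead mutual-information matrix
#'
#' Pairwise MI between the 12 lead feature rows; the diagonal holds each
#' lead's own entropy (`I(X;X) = H[X]`), which later acts as a self-loop
#' weight in the lead graph.
#'
#' @param features A `lead_features` object (12 rows).
#' @param cfg A [discretization_config()].
#' @return An object of class `mi_matrix` with a symmetric 12 x 12 `values`
#'   matrix in bits.
#' @export
mi_matrix <- function(features, cfg = discretization_config()) {
  f <- features$features
  if (nrow(f) != 12) stop("feature matrix must have 12 rows")
  syms <- lapply(seq_len(nrow(f)), function(i) discretize(f[i, ], cfg))
  H <- vapply(syms, symbol_entropy, 0)
  n <- nrow(f)
  m <- matrix(0, n, n, dimnames = list(features$lead_names,
                                       features$lead_names))
  for (i in seq_len(n)) {
    m[i, i] <- H[i]
    for (j in seq_len(n)) {
      if (j <= i) next
      mij <- H[i] + H[j] - joint_entropy(syms[[i]], syms[[j]])
      m[i, j] <- mij
      m[j, i] <- mij
    }
  }
  structure(list(values = m, discretization = cfg,
                 lead_names = features$lead_names),
            class = "mi_matrix")
}

#' Pairwise lead-similarity matrix under alternative metrics
#'
#' Comparison mode against MI: Pearson correlation, cosine similarity, or
#' Euclidean distance converted to a similarity `1/(1 + d)` so that larger
#' always means more similar.
#'
#' @param features A `lead_features` object.
#' @param metric One of `"mi"`, `"pearson"`, `"cosine"`, `"euclidean"`.
#' @param cfg Discretization config (used for `"mi"` only).
#' @return N x N numeric matrix.
#' @export
similarity_matrix <- function(features,
                              metric = c("mi", "pearson", "cosine",
                                         "euclidean"),
                              cfg = discretization_config()) {
  metric <- match.arg(metric)
  f <- features$features
  out <- switch(metric,
    mi = mi_matrix(features, cfg)$values,
    pearson = stats::cor(t(f)),
    cosine = {
      nrm <- sqrt(rowSums(f^2))
      (f %*% t(f)) / outer(nrm, nrm)
    },
    euclidean = 1 / (1 + as.matrix(stats::dist(f))))
  dimnames(out) <- list(features$lead_names, features$lead_names)
  out
}

#' Threshold an MI matrix into a graph adjacency
#'
#' Entries strictly greater than `tau` are kept verbatim; the rest are
#' zeroed. The diagonal (self-entropy) is treated like any other entry, so
#' any `tau` below the lead entropies leaves self-loops in place.
#'
#' @param mi An `mi_matrix` or plain numeric matrix.
#' @param tau Non-negative threshold. Default 0 keeps every positive MI edge
#'   (the 12-lead graph is naturally dense).
#' @return An object of class `adjacency_matrix`.
#' @export
threshold_adjacency <- function(mi, tau = 0) {
  if (tau < 0) stop("tau must be >= 0")
  m <- if (inherits(mi, "mi_matrix")) mi$values else as.matrix(mi)
  a <- ifelse(m > tau, m, 0)
  structure(list(values = a, tau = tau), class = "adjacency_matrix")
}

#' Symmetric normalization of an adjacency matrix
#'
#' Computes `D^{-1/2} A D^{-1/2}` with `D = diag(row sums of A)`. The result
#' is symmetric with spectral radius at most 1.
#'
#' @param adj An `adjacency_matrix` or plain non-negative matrix.
#' @return An object of class `norm_adjacency` with `values` and `degrees`.
#' @export
normalize_adjacency <- function(adj) {
  a <- if (inherits(adj, "adjacency_matrix")) adj$values else as.matrix(adj)
  d <- rowSums(a)
  if (any(d <= 0))
    stop("isolated node; lower tau or enable self-loops")
  dinv <- 1 / sqrt(d)
  ahat <- a * outer(dinv, dinv)
  structure(list(values = ahat, degrees = d), class = "norm_adjacency")
}

#' Polynomial graph filter H = h0 I + h1 A + ... + hk A^k
#'
#' @param adj Square numeric matrix A.
#' @param coefficients Numeric vector `(h0, ..., hk)`; the polynomial degree
#'   is `length(coefficients) - 1`.
#' @return The N x N filter matrix, built by Horner-style iterated
#'   multiplication.
#' @export
polynomial_filter <- function(adj, coefficients) {
  a <- as.matrix(adj)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  k <- length(coefficients) - 1
  h <- diag(coefficients[k + 1], nrow(a))
  if (k > 0) for (i in k:1) h <- h %*% a + diag(coefficients[i], nrow(a))
  h
}

#' Apply a graph filter to vertex features: Vout = H Vin
#'
#' @param filter_matrix N x N filter (e.g. from [polynomial_filter()]).
#' @param vertex_features N x F node feature matrix.
#' @return N x F filtered features.
#' @export
apply_filter <- function(filter_matrix, vertex_features) {
  h <- as.matrix(filter_matrix)
  v <- as.matrix(vertex_features)
  if (ncol(h) != nrow(v)) stop("shape mismatch")
  h %*% v
}

#' Lead graph for a recording: features -> MI -> threshold -> normalize
#'
#' @param features A `lead_features` object.
#' @param tau Adjacency threshold, see [threshold_adjacency()].
#' @param cfg Discretization config.
#' @return A `norm_adjacency`.
#' @export
lead_graph <- function(features, tau = 0, cfg = discretization_config()) {
  normalize_adjacency(threshold_adjacency(mi_matrix(features, cfg), tau))
}

#' Cohort-average lead graph
#'
#' Averages the per-recording MI matrices of a cohort, then thresholds and
#' normalizes once; the alternative reading in which a single shared 12 x 12
#' graph backs every recording.
#'
#' @param features_list List of `lead_features`.
#' @inheritParams lead_graph
#' @return A `norm_adjacency`.
#' @export
cohort_graph <- function(features_list, tau = 0,
                         cfg = discretization_config()) {
  ms <- lapply(features_list, function(f) mi_matrix(f, cfg)$values)
  avg <- Reduce(`+`, ms) / length(ms)
  normalize_adjacency(threshold_adjacency(avg, tau))
}

#' Write / read a lead-indexed square matrix as CSV
#'
#' Values are printed with 12 significant digits so the round trip is
#' lossless at that precision; a provenance hash can be embedded as a
#' comment.
#'
#' @param m An `mi_matrix`, `adjacency_matrix`, `norm_adjacency`, or matrix.
#' @param path Output file.
#' @param config_hash Optional provenance string.
#' @export
write_mi_csv <- function(m, path, config_hash = NULL) {
  v <- if (is.matrix(m)) m else m$values
  write_matrix_csv(v, path, config_hash = config_hash)
}

#' @rdname write_mi_csv
#' @return `read_mi_csv` returns the numeric matrix with lead-name dimnames.
#' @export
read_mi_csv <- function(path) {
  read_matrix_csv(path)$mat
}
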