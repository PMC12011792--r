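test_that("discretize covers forced, degenerate and equal-frequency cases", {
  cfg4 <- discretization_config(n_bins = 4)
  expect_identical(discretize(c(0, 1, 2, 3), cfg4), c(0L, 1L, 2L, 3L))
  expect_identical(discretize(rep(2.5, 10), cfg4), integer(10))

  set.seed(99)
  x <- rnorm(800)
  sym <- discretize(x, discretization_config(8, "equal_frequency"))
  counts <- tabulate(sym + 1L, nbins = 8)
  expect_lte(diff(range(counts)), 1)
  expect_true(all(sym >= 0 & sym < 8))
})

test_that("joint and conditional entropy match closed forms and oracles", {
  x <- c(0L, 0L, 1L, 1L)
  y <- c(0L, 1L, 0L, 1L)
  expect_equal(joint_entropy(x, y), 2.0)
  expect_equal(joint_entropy(rep(0L, 5), rep(3L, 5)), 0)
  expect_equal(conditional_entropy(x, x), 0)
  expect_equal(conditional_entropy(x, y), 1.0)
  expect_error(joint_entropy(x, y[1:3]), "mismatch")

  set.seed(5)
  for (i in 1:5) {
    xs <- sample(0:3, 60, replace = TRUE)
    ys <- sample(0:2, 60, replace = TRUE)
    expect_equal(joint_entropy(xs, ys), joint_entropy_oracle(xs, ys),
                 tolerance = 1e-12)
    # chain rule and the direct conditional-probability sum agree
    expect_equal(conditional_entropy(xs, ys),
                 conditional_entropy_oracle(xs, ys), tolerance = 1e-12)
  }
})

test_that("mutual information: identities, symmetry, oracle agreement", {
  cfg4 <- discretization_config(n_bins = 4)
  x <- c(0, 1, 2, 3, 0, 1, 2, 3)
  expect_equal(mutual_information(x, x, cfg4), 2.0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1),
                                  discretization_config(n_bins = 2)), 0)

  set.seed(31)
  x <- rnorm(500)
  y <- x + rnorm(500, sd = 0.5)
  cfg <- discretization_config()
  xs <- discretize(x, cfg); ys <- discretize(y, cfg)
  expect_equal(mutual_information(x, y, cfg), mi_oracle(xs, ys),
               tolerance = 1e-12)
  expect_equal(mutual_information(x, y, cfg), mutual_information(y, x, cfg),
               tolerance = 1e-12)
})

test_that("mi_matrix is symmetric 12x12 with entropies on the diagonal", {
  f <- tiny_features()[[1]]
  m <- mi_matrix(f)
  expect_equal(dim(m$values), c(12, 12))
  expect_lt(max(abs(m$values - t(m$values))), 1e-9)
  expect_true(all(m$values >= -1e-12))
  cfg <- m$discretization
  for (i in c(1, 5, 12))
    expect_equal(m$values[i, i],
                 symbol_entropy(discretize(f$features[i, ], cfg)),
                 tolerance = 1e-9)

  # duplicated rows give M[i, j] = M[i, i]
  g <- f
  g$features[2, ] <- g$features[1, ]
  m2 <- mi_matrix(g)
  expect_equal(m2$values[1, 2], m2$values[1, 1], tolerance = 1e-9)

  # independent white noise rows: off-diagonal MI clearly below diagonal
  set.seed(8)
  h <- f
  h$features <- t(apply(matrix(rnorm(12 * 2570), 12), 1, zscore))
  rownames(h$features) <- f$lead_names
  m3 <- mi_matrix(h)$values
  off <- m3[row(m3) != col(m3)]
  expect_lt(max(off), min(diag(m3)))
  # and correlated leads carry more MI than independent noise
  expect_gt(min(m$values[row(m$values) != col(m$values)]), max(off))
})

test_that("similarity_matrix implements the alternative metrics", {
  f <- tiny_features()[[1]]
  p <- similarity_matrix(f, "pearson")
  expect_equal(unname(diag(p)), rep(1, 12))
  expect_true(all(p >= -1 - 1e-12 & p <= 1 + 1e-12))

  o <- f
  o$features <- diag(12)          # pairwise orthogonal rows
  rownames(o$features) <- f$lead_names
  cs <- similarity_matrix(o, "cosine")
  expect_equal(cs[1, 2], 0)
  expect_equal(unname(diag(cs)), rep(1, 12))

  e <- similarity_matrix(f, "euclidean")
  expect_equal(unname(diag(e)), rep(1, 12))   # d = 0 -> similarity 1
  expect_true(all(e > 0 & e <= 1))

  expect_error(similarity_matrix(f, "hamming"))
})

test_that("threshold_adjacency implements the tau rule", {
  f <- tiny_features()[[1]]
  m <- mi_matrix(f)
  a0 <- threshold_adjacency(m, 0)
  expect_equal(a0$values, m$values)          # all-positive MI, tau 0 no-op

  amax <- threshold_adjacency(m, max(m$values))
  expect_true(all(amax$values == 0))

  m2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(threshold_adjacency(m2, 0.6)$values, diag(2))
  expect_error(threshold_adjacency(m2, -1), "tau")
})

test_that("normalize_adjacency matches hand arithmetic and spectra", {
  expect_equal(normalize_adjacency(diag(3))$values, diag(3))
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(a)$values, a)
  b <- matrix(c(2, 1, 1, 3), 2)
  nb <- normalize_adjacency(b)
  expect_equal(nb$values,
               matrix(c(2 / 3, 1 / sqrt(12), 1 / sqrt(12), 3 / 4), 2),
               tolerance = 1e-12)
  expect_equal(nb$degrees, c(3, 4))

  iso <- matrix(c(1, 0, 0, 0), 2)
  expect_error(normalize_adjacency(iso), "isolated")
})

test_that("polynomial_filter and apply_filter match brute-force oracles", {
  a_path <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(polynomial_filter(a_path, 1), diag(3))
  expect_equal(polynomial_filter(a_path, c(0, 1)), a_path)
  expect_equal(polynomial_filter(a_path, c(1, 1, 1)),
               matrix(c(2, 1, 1, 1, 3, 1, 1, 1, 2), 3))

  v <- matrix(1:6, 3)
  expect_equal(apply_filter(diag(3), v), v)
  expect_equal(apply_filter(matrix(0, 3, 3), v), matrix(0, 3, 2))
  expect_error(apply_filter(diag(3), matrix(1, 2, 2)), "mismatch")

  set.seed(17)
  for (i in 1:25) {
    h <- matrix(rnorm(25), 5)
    vin <- matrix(rnorm(20), 5)
    expect_equal(apply_filter(h, vin), matmul_oracle(h, vin),
                 tolerance = 1e-12)
    coef <- rnorm(4)
    a <- matrix(rnorm(25), 5)
    hp <- polynomial_filter(a, coef)
    oracle <- coef[1] * diag(5) +
      coef[2] * a +
      coef[3] * matmul_oracle(a, a) +
      coef[4] * matmul_oracle(matmul_oracle(a, a), a)
    expect_equal(hp, oracle, tolerance = 1e-9)
  }
})

test_that("MI matrix CSV round-trips to 12 significant digits", {
  f <- tiny_features()[[1]]
  m <- mi_matrix(f)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mi_csv(m, path, config_hash = "deadbeef")
  back <- read_mi_csv(path)
  expect_equal(back, m$values, tolerance = 1e-11)
  expect_identical(colnames(back), f$lead_names)
})
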