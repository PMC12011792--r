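# Small seeded fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

# tiny cohort: 4 subjects x 2 recordings, default noise, 10 s @ 257 Hz
tiny_cohort <- function(seed = 42, n_subjects = 4, per_subject = 2,
                        noise = noise_spec()) {
  generate_cohort(n_subjects = n_subjects,
                  recordings_per_subject = per_subject,
                  noise = noise, seed = seed)
}

# cache preprocessed features of the tiny cohort (built once per test run)
tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(tiny_cohort(), preprocess_recording)
    cache
  }
})

# short recordings keep classifier tests fast: 2 s @ 257 Hz
short_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(n_subjects = 3, recordings_per_subject = 3,
                                duration = 2, seed = 7)
      cache <<- lapply(cohort, extract_features)
    }
    cache
  }
})

rms <- function(x) sqrt(mean(x^2))

# row-wise population z-score for matrices (comparison on a common scale)
scale_rows <- function(m) {
  t(apply(m, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
}

# brute-force O(n^2) matrix product oracle
matmul_oracle <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      for (k in seq_len(ncol(a)))
        out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# independent joint-entropy oracle: explicit double loop over the histogram
joint_entropy_oracle <- function(xs, ys) {
  h <- 0
  n <- length(xs)
  for (x in unique(xs)) for (y in unique(ys)) {
    p <- sum(xs == x & ys == y) / n
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# direct evaluation of the conditional-entropy sum -p(x,y) log2 p(x|y)
conditional_entropy_oracle <- function(xs, ys) {
  n <- length(xs)
  h <- 0
  for (x in unique(xs)) for (y in unique(ys)) {
    pxy <- sum(xs == x & ys == y) / n
    py <- sum(ys == y) / n
    if (pxy > 0) h <- h - pxy * log2(pxy / py)
  }
  h
}

# direct evaluation of the pointwise-MI sum over the joint histogram
mi_oracle <- function(xs, ys) {
  n <- length(xs)
  s <- 0
  for (x in unique(xs)) for (y in unique(ys)) {
    pxy <- sum(xs == x & ys == y) / n
    if (pxy > 0) {
      px <- sum(xs == x) / n
      py <- sum(ys == y) / n
      s <- s + pxy * log2(pxy / (px * py))
    }
  }
  s
}

# two-sided p value for a t statistic by numerical integration of the t density
t_pvalue_oracle <- function(t_stat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
}
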