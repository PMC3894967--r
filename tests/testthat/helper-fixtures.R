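# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately take the slow, textbook route (full covariance
# eigendecomposition, per-pair cor.test, explicit formulas) so they stay
# independent of the package's vectorized implementations.

# deterministic small matrix with named probes/samples
tiny_matrix <- function(n_probes = 6, n_samples = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_probes * n_samples, mean = 7, sd = 1.5),
                n_probes, n_samples)
  })
  dimnames(m) <- list(sprintf("probe%02d", seq_len(n_probes)),
                      sprintf("S%d", seq_len(n_samples)))
  m
}

# exactly rank-1 z-scored matrix: row g = u_g * v / sd(v)
rank1_z <- function(u = c(1, -1, 2, -2, 0.5, 3), v = c(-1, 0, 1, 2)) {
  vc <- v - mean(v)
  z <- outer(u / abs(u), vc / sd(vc))   # unit-sd rows, direction v
  dimnames(z) <- list(sprintf("probe%02d", seq_along(u)),
                      sprintf("S%d", seq_along(v)))
  z
}

# brute-force PCA over samples: eigendecomposition of the full
# probe-space covariance matrix, scores = projections of the samples
oracle_pca1 <- function(z) {
  X <- t(z)                              # samples x probes
  C <- stats::cov(X)                     # probes x probes
  ee <- eigen(C, symmetric = TRUE)
  scores <- drop(scale(X, center = TRUE, scale = FALSE) %*% ee$vectors[, 1])
  list(scores = scores / stats::sd(scores),
       variance_explained = pmax(ee$values, 0) / sum(pmax(ee$values, 0)))
}

# per-pair connectivity by looping cor.test
oracle_connectivity <- function(z, alpha = 0.001) {
  G <- nrow(z)
  n_conn <- integer(G)
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      p <- stats::cor.test(z[i, ], z[j, ])$p.value
      if (p < alpha) {
        n_conn[i] <- n_conn[i] + 1L
        n_conn[j] <- n_conn[j] + 1L
      }
    }
  }
  n_conn
}

# textbook Welch statistic
oracle_welch <- function(x, y) {
  v1 <- var(x); v2 <- var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = tstat, df = df, p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# Spearman with average ranks as rank-then-Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# small synthetic study for fast tests
small_study <- function(seed = 1, n_probes = 2000, ...) {
  generate_study(generator_params(seed = seed, n_probes = n_probes, ...))
}

# region matrix -> z-scored (constant rows silently dropped)
zprep <- function(m) zscore_rows(suppressWarnings(drop_constant_rows(m)))
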