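# Independent oracles used across tests.  These are deliberately naive
# implementations kept separate from the package code paths they check.

# closed-form one-way ANOVA from the sum-of-squares decomposition
anova_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# brute-force average-linkage (UPGMA) agglomeration on a dissimilarity
# matrix: at each step merge the pair of clusters with the smallest mean
# pairwise original distance.  Returns merge heights and the partition
# (cluster membership over original items) after each merge.
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          h <- mean(d[clusters[[a]], clusters[[b]]])
          if (h < bh) { bh <- h; best <- c(a, b) }
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bh)
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# co-membership matrix of a partition (permutation-invariant comparison)
comembership <- function(part) outer(part, part, `==`)

# construct vectors of length m with exact empirical correlation structure:
# given a target correlation matrix R (via its Cholesky factor), returns a
# matrix whose columns have zero mean, unit norm, and empirical
# correlations equal to R up to floating point.
vectors_with_cor <- function(R, m, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  raw <- matrix(rnorm(m * p), m, p)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))                 # orthonormal, zero-mean columns
  v <- q %*% chol(R)
  scale(v, center = FALSE, scale = sqrt(colSums(v^2)))
}

# minimal hand-built decomposition object for unit tests that exercise the
# integration stage in isolation
fake_decomp <- function(contributions, layer, sample_ids = NULL,
                        feature_scores = NULL, centering = "none") {
  K <- nrow(contributions)
  M <- ncol(contributions)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(M))
  dimnames(contributions) <- list(paste0("PC", seq_len(K)), sample_ids)
  if (is.null(feature_scores)) {
    feature_scores <- matrix(0, 2L, K,
                             dimnames = list(c("fA", "fB"), paste0("PC", seq_len(K))))
  }
  structure(list(layer = layer, sample_ids = sample_ids,
                 feature_ids = rownames(feature_scores),
                 contributions = contributions,
                 feature_scores = feature_scores,
                 variance_fraction = rep(1 / K, K),
                 centering = centering, n_components = K),
            class = "pc_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reduced-size generator configuration for fast unit tests (defaults are
# exercised in the acceptance suite)
small_config <- function(seed = 1, ...) {
  synthetic_config(
    n_features = c(compound = 60L, mRNA = 300L, miRNA = 80L),
    n_planted_tumor = c(compound = 5L, mRNA = 12L, miRNA = 6L),
    n_planted_icc = c(compound = 5L, mRNA = 12L, miRNA = 6L),
    seed = seed, ...)
}

# log2-transformed copy of a dataset's layers (generator output is linear)
log_layers <- function(ds) {
  lapply(ds$layers, function(m)
    omics_matrix(log2(unclass(m)), omics_layer(m)))
}
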