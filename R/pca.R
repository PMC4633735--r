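#' Feature-space principal component analysis of one omics layer
#'
#' Performs the "feature as point" orientation of PCA: each of the N
#' features of a layer is treated as a point in the M-dimensional sample
#' space.  The decomposition of the (optionally feature-centered) N x M
#' matrix X by singular values, \eqn{X = U D V'}, yields for every component
#' k a *sample contribution vector* \eqn{CX^k} (the k-th right singular
#' vector, an M-vector with one entry per sample) and a *feature score*
#' \eqn{PCX_i^k = (U D)_{ik}} (feature i's coordinate along component k).
#' With M samples there are at most M components; a 32-sample cohort yields
#' at most 32 components per layer.
#'
#' Centering subtracts each feature's mean across samples (the default), so
#' components describe between-sample contrast; `center = "none"` analyses
#' the raw values.  Components whose singular value is numerically zero
#' relative to the largest (factor 1e-12) are dropped and the realized
#' component count is reported in the result.
#'
#' The SVD sign is arbitrary; for reproducibility each contribution vector
#' is oriented so that its largest-magnitude entry is positive (feature
#' scores are flipped accordingly, preserving the reconstruction).
#'
#' @param m an [omics_matrix()] with at least 2 features and 2 samples.
#' @param center `"feature_mean"` (default) or `"none"`.
#' @return an object of class `pc_decomposition`: a list with
#'   \describe{
#'     \item{layer}{layer tag of `m`.}
#'     \item{sample_ids}{sample identifiers (length M).}
#'     \item{feature_ids}{feature identifiers (length N).}
#'     \item{contributions}{K x M matrix; row k is the orthonormal sample
#'       contribution vector CX^k.}
#'     \item{feature_scores}{N x K matrix of per-feature scores PCX.}
#'     \item{variance_fraction}{length-K vector, non-increasing, summing to
#'       at most 1.}
#'     \item{centering}{the centering mode used.}
#'     \item{n_components}{K, the number of retained components.}
#'   }
#' @examples
#' ds <- simulate_multiomics(synthetic_config(
#'   n_features = c(compound = 40, mRNA = 60, miRNA = 30),
#'   n_planted_tumor = c(compound = 4, mRNA = 6, miRNA = 3),
#'   n_planted_icc = c(compound = 4, mRNA = 6, miRNA = 3)))
#' d <- pca_decompose(ds$layers$compound)
#' d$variance_fraction[1:3]
#' @export
pca_decompose <- function(m, center = c("feature_mean", "none")) {
  stopifnot(inherits(m, "omics_matrix"))
  center <- match.arg(center)
  x <- unclass(m)
  attr(x, "layer") <- NULL
  attr(x, "symbols") <- NULL
  if (nrow(x) < 2L || ncol(x) < 2L) abort("need at least 2 features and 2 samples")
  if (any(!is.finite(x))) abort("non-finite values")
  if (center == "feature_mean") x <- x - rowMeans(x)

  s <- svd(x)
  tol <- max(s$d) * 1e-12
  keep <- which(s$d > tol)
  if (length(keep) == 0L) {
    abort("matrix is identically zero after centering; no components")
  }
  d <- s$d[keep]
  v <- s$v[, keep, drop = FALSE]          # M x K, columns = CX^k
  u <- s$u[, keep, drop = FALSE]

  # deterministic sign: largest-|entry| of each contribution vector positive
  for (k in seq_along(keep)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  contributions <- t(v)
  scores <- sweep(u, 2L, d, `*`)
  K <- length(keep)
  dimnames(contributions) <- list(paste0("PC", seq_len(K)), colnames(m))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(K)))
  varfrac <- s$d^2 / sum(s$d^2)

  structure(list(layer = omics_layer(m),
                 sample_ids = colnames(m),
                 feature_ids = rownames(m),
                 contributions = contributions,
                 feature_scores = scores,
                 variance_fraction = varfrac[keep],
                 centering = center,
                 n_components = K),
            class = "pc_decomposition")
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat(sprintf("pc_decomposition [%s]: %d features, %d samples, %d components (centering: %s)\n",
              x$layer, length(x$feature_ids), length(x$sample_ids),
              x$n_components, x$centering))
  vf <- x$variance_fraction[seq_len(min(5L, x$n_components))]
  cat("variance fraction:", paste(sprintf("PC%d %.3f", seq_along(vf), vf),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Two-dimensional embedding of features along two components
#'
#' Returns each feature's score pair along two distinct components of a
#' decomposition — the plane used both for outlier visualisation and for
#' two-axis feature selection (e.g. compounds in the PC2-PC3 plane, miRNA in
#' PC1-PC2).
#'
#' @param d a [pca_decompose()] result.
#' @param k1,k2 distinct 1-based component indices.
#' @return a data frame with columns `feature_id`, `x` (score along `k1`)
#'   and `y` (score along `k2`).
#' @export
embed2d <- function(d, k1, k2) {
  stopifnot(inherits(d, "pc_decomposition"))
  for (k in c(k1, k2)) {
    if (!(is.numeric(k) && length(k) == 1L && k >= 1 && k <= d$n_components &&
          k == as.integer(k))) {
      abort("component index out of range (1..%d)", d$n_components)
    }
  }
  if (k1 == k2) abort("k1 and k2 must differ (degenerate plane)")
  data.frame(feature_id = d$feature_ids,
             x = d$feature_scores[, k1],
             y = d$feature_scores[, k2],
             stringsAsFactors = FALSE)
}

#' Write a decomposition's tables as delimited text
#'
#' Writes the sample contribution matrix (components x samples) and the
#' feature score matrix (features x components), keyed by identifiers.
#'
#' @param d a [pca_decompose()] result.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_pc_decomposition <- function(d, dir, sep = "\t") {
  stopifnot(inherits(d, "pc_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctab <- data.frame(component = rownames(d$contributions),
                     d$contributions, check.names = FALSE)
  utils::write.table(ctab, file.path(dir, paste0(d$layer, "_contributions.tsv")),
                     sep = sep, quote = FALSE, row.names = FALSE)
  stab <- data.frame(feature_id = rownames(d$feature_scores),
                     d$feature_scores, check.names = FALSE)
  utils::write.table(stab, file.path(dir, paste0(d$layer, "_feature_scores.tsv")),
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(dir)
}
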