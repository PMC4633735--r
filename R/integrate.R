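#' Cluster pooled sample-contribution vectors across omics layers
#'
#' Pools every component's sample contribution vector from every layer
#' (e.g. 3 layers x 32 components = 96 vectors over the same 32 samples),
#' computes the Pearson correlation r between every pair over the shared
#' samples, and clusters them by UPGMA (average linkage) on the distance
#' d = 1 - |r|.  The absolute value makes anticorrelated components
#' proximate: a contribution vector and its negation describe the same
#' sample contrast.
#'
#' Components from the same layer have exactly orthogonal (and, under
#' feature-mean centering, exactly uncorrelated) contribution vectors, so
#' any cluster structure is driven by *cross-layer* correlation; this
#' within-layer zero-correlation invariant is asserted on every run when all
#' decompositions are feature-centered.
#'
#' @param decomps list of [pca_decompose()] results sharing one sample order
#'   (run [align_layers()] first).
#' @param max_k optional cap on the component index taken from each layer
#'   (`NULL` = all components).
#' @return an object of class `pc_tree`: a list with
#'   \describe{
#'     \item{labels}{data frame `label` ("PC<k>_<layer>"), `layer`, `k`.}
#'     \item{cor}{pooled correlation matrix r.}
#'     \item{dist}{distance matrix 1 - |r| (zero diagonal, symmetric).}
#'     \item{hclust}{the UPGMA merge tree (`stats::hclust`, average linkage).}
#'   }
#' @export
build_pc_tree <- function(decomps, max_k = NULL) {
  stopifnot(is.list(decomps), length(decomps) >= 1L)
  lapply(decomps, function(d) stopifnot(inherits(d, "pc_decomposition")))
  ref <- decomps[[1L]]$sample_ids
  for (d in decomps) {
    if (!identical(d$sample_ids, ref)) {
      abort("decompositions have mismatched sample orders (layer '%s'); run align_layers() first",
            d$layer)
    }
  }
  rows <- list(); lab <- list()
  for (d in decomps) {
    kk <- seq_len(d$n_components)
    if (!is.null(max_k)) kk <- kk[kk <= max_k]
    if (length(kk) == 0L) next
    rows[[length(rows) + 1L]] <- d$contributions[kk, , drop = FALSE]
    lab[[length(lab) + 1L]] <- data.frame(
      label = sprintf("PC%d_%s", kk, d$layer),
      layer = d$layer, k = kk, stringsAsFactors = FALSE)
  }
  C <- do.call(rbind, rows)
  labels <- do.call(rbind, lab)
  if (is.null(C) || nrow(C) < 2L) abort("fewer than 2 components in total")
  rownames(C) <- labels$label

  r <- stats::cor(t(C))
  # within-layer contributions are orthonormal with zero mean under
  # feature-mean centering, hence exactly uncorrelated
  if (all(vapply(decomps, function(d) d$centering, "") == "feature_mean")) {
    for (ly in unique(labels$layer)) {
      idx <- which(labels$layer == ly)
      if (length(idx) > 1L) {
        off <- abs(r[idx, idx])[upper.tri(diag(length(idx)))]
        if (any(off > 1e-8)) {
          abort("within-layer components of '%s' are not uncorrelated (max |r| = %.2e)",
                ly, max(off))
        }
      }
    }
  }
  d <- 1 - abs(r)
  d <- (d + t(d)) / 2          # enforce exact symmetry
  d[d < 0] <- 0
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(labels = labels, cor = r, dist = d, hclust = hc),
            class = "pc_tree")
}

#' @export
print.pc_tree <- function(x, ...) {
  cat(sprintf("pc_tree: %d components from %d layers (%s); UPGMA on 1 - |r|\n",
              nrow(x$labels), length(unique(x$labels$layer)),
              paste(unique(x$labels$layer), collapse = ", ")))
  invisible(x)
}

#' Export a component tree in Newick format
#'
#' @param tree a [build_pc_tree()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pc_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "pc_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}

#' Select the coherent cross-layer component cluster
#'
#' Cuts the UPGMA tree at `cut_height` and, among the resulting clusters
#' that contain components from at least `min_layers` distinct layers,
#' chooses the one with the largest mean pairwise |r| (the most tightly
#' correlated cluster); ties are broken in favour of the smallest sum of
#' component indices, since lower-index components carry more variance.
#' An optional `max_k` removes members with component index above the cap
#' before clusters are scored.
#'
#' @param tree a [build_pc_tree()] result.
#' @param cut_height tree cut height in (0, 1); clusters merged below this
#'   distance stay together.
#' @param min_layers minimum number of distinct layers a candidate cluster
#'   must span.
#' @param max_k optional cap on member component indices.
#' @return an object of class `selected_pc_set`: list with `members` (data
#'   frame `label`, `layer`, `k`), `cluster_mean_abs_r`, and `cut_height`.
#' @export
select_pcs <- function(tree, cut_height = 0.6, min_layers = 2L, max_k = NULL) {
  stopifnot(inherits(tree, "pc_tree"))
  if (!(cut_height > 0 && cut_height < 1)) abort("cut_height must be in (0,1)")
  if (min_layers < 1L) abort("min_layers must be >= 1")
  grp <- stats::cutree(tree$hclust, h = cut_height)
  labels <- tree$labels
  cand <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (!is.null(max_k)) idx <- idx[labels$k[idx] <= max_k]
    if (length(idx) < 2L) next
    if (length(unique(labels$layer[idx])) < min_layers) next
    absr <- abs(tree$cor[idx, idx])
    mean_r <- mean(absr[upper.tri(absr)])
    cand[[length(cand) + 1L]] <- list(idx = idx, mean_r = mean_r,
                                      sum_k = sum(labels$k[idx]))
  }
  if (length(cand) == 0L) {
    feasible <- .nearest_feasible_cut(tree, min_layers, max_k)
    abort("no cluster spans >= %d layers at cut height %.3f%s",
          min_layers, cut_height,
          if (is.finite(feasible))
            sprintf(" (nearest feasible cut height: %.3f)", feasible) else "")
  }
  mean_rs <- vapply(cand, `[[`, 0, "mean_r")
  best <- which(mean_rs == max(mean_rs))
  if (length(best) > 1L) {
    sum_ks <- vapply(cand[best], `[[`, 0, "sum_k")
    best <- best[which.min(sum_ks)]
  }
  ch <- cand[[best[1L]]]
  structure(list(members = labels[ch$idx, , drop = FALSE],
                 cluster_mean_abs_r = ch$mean_r,
                 cut_height = cut_height),
            class = "selected_pc_set")
}

# smallest merge height at which some cluster spans >= min_layers layers
.nearest_feasible_cut <- function(tree, min_layers, max_k = NULL) {
  hs <- sort(unique(tree$hclust$height))
  labels <- tree$labels
  for (h in hs) {
    grp <- stats::cutree(tree$hclust, h = h)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (!is.null(max_k)) idx <- idx[labels$k[idx] <= max_k]
      if (length(idx) >= 2L &&
          length(unique(labels$layer[idx])) >= min_layers) {
        return(h)
      }
    }
  }
  Inf
}

#' @export
print.selected_pc_set <- function(x, ...) {
  cat(sprintf("selected_pc_set: %d components (%s); mean |r| = %.3f at cut %.2f\n",
              nrow(x$members), paste(x$members$label, collapse = ", "),
              x$cluster_mean_abs_r, x$cut_height))
  invisible(x)
}

#' Categorical regression of a component's sample contributions on class
#'
#' Regresses the contribution vector \eqn{CX^k} on the four class
#' indicators \eqn{\delta_{a,i}} with cell-means coding (no intercept):
#' the fitted coefficient \eqn{b_a} is the class-a mean contribution, and
#' the F statistic against the grand-mean-only model is algebraically the
#' one-way ANOVA F across the classes.  Categorical coding is used rather
#' than a numeric class score because neither the order nor the spacing of
#' the groups is known a priori.
#'
#' @param d a [pca_decompose()] result.
#' @param k 1-based component index.
#' @param design a [sample_design()] covering the decomposition's samples;
#'   every class must be present (at least 2 samples per class for a finite
#'   F).
#' @return an object of class `categorical_fit`: list with `pc` (label),
#'   `coefficients` (named per-class means b_a), `F_statistic`, `p_value`,
#'   `df1`, `residual_df`.
#' @export
categorical_regression <- function(d, k, design) {
  stopifnot(inherits(d, "pc_decomposition"), inherits(design, "sample_design"))
  if (!(k >= 1 && k <= d$n_components)) {
    abort("component index out of range (1..%d)", d$n_components)
  }
  .check_design_matches(design, d$sample_ids)
  cls <- design$class[match(d$sample_ids, design$sample_id)]
  if (any(table(cls) == 0L)) {
    abort("class(es) absent from design: %s",
          .listing(levels(cls)[table(cls) == 0L]))
  }
  cx <- d$contributions[k, ]
  fit <- stats::lm(cx ~ 0 + cls)
  b <- stats::coef(fit)
  names(b) <- sub("^cls", "", names(b))

  null_fit <- stats::lm(cx ~ 1)
  df1 <- nlevels(cls) - 1L
  df2 <- length(cx) - nlevels(cls)
  ssw <- sum(stats::resid(fit)^2)
  ssb <- sum(stats::resid(null_fit)^2) - ssw
  tot <- ssb + ssw
  if (tot <= .Machine$double.eps * length(cx)) {
    # constant contributions: no between- or within-class variation
    Fstat <- 0; pval <- 1
  } else if (ssw <= tot * 1e-14) {
    warning("zero residual variance; p-value reported as 0-limit")
    Fstat <- Inf; pval <- 0
  } else {
    a <- stats::anova(null_fit, fit)
    Fstat <- a$F[2L]
    pval <- a$`Pr(>F)`[2L]
  }
  structure(list(pc = sprintf("PC%d_%s", k, d$layer),
                 coefficients = b,
                 F_statistic = Fstat,
                 p_value = pval,
                 df1 = df1,
                 residual_df = df2),
            class = "categorical_fit")
}

#' @export
print.categorical_fit <- function(x, ...) {
  cat(sprintf("categorical_fit %s: F(%d, %d) = %.4g, p = %.3g\n",
              x$pc, x$df1, x$residual_df, x$F_statistic, x$p_value))
  cat("class means:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pairwise correlation table of the selected components
#'
#' For every pair of selected components, the Pearson correlation of their
#' sample contribution vectors over the shared samples and its two-sided
#' p-value (t distribution with M - 2 degrees of freedom) — the numbers
#' shown beside a scatter-matrix of the selected components.
#'
#' @param selected a [select_pcs()] result.
#' @param decomps list of [pca_decompose()] results containing the selected
#'   layers.
#' @return data frame with columns `pc1`, `pc2`, `r`, `p_value`; one row per
#'   unordered pair (including self-pairs, for which r = 1 and p is NA).
#' @export
scatter_report <- function(selected, decomps) {
  stopifnot(inherits(selected, "selected_pc_set"))
  names(decomps) <- vapply(decomps, function(d) d$layer, "")
  mem <- selected$members
  if (nrow(mem) == 0L) abort("empty selection")
  vecs <- lapply(seq_len(nrow(mem)), function(i) {
    d <- decomps[[mem$layer[i]]]
    if (is.null(d)) abort("no decomposition for layer '%s'", mem$layer[i])
    d$contributions[mem$k[i], ]
  })
  n <- nrow(mem)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      out[[length(out) + 1L]] <- data.frame(pc1 = mem$label[i],
                                            pc2 = mem$label[j],
                                            r = 1, p_value = NA_real_)
    } else {
      ct <- stats::cor.test(vecs[[i]], vecs[[j]], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(pc1 = mem$label[i],
                                            pc2 = mem$label[j],
                                            r = unname(ct$estimate),
                                            p_value = ct$p.value)
    }
  }
  do.call(rbind, out)
}
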