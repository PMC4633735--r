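#' Integrated multi-omics component analysis
#'
#' Runs the full unsupervised integration on a set of matched omics layers:
#' aligns every layer to the design's sample order, decomposes each layer
#' by feature-space PCA ([pca_decompose()]), pools all sample-contribution
#' vectors and clusters them by UPGMA on 1 - |r| ([build_pc_tree()]),
#' selects the coherent cross-layer component cluster ([select_pcs()]),
#' validates each selected component's class separation by categorical
#' regression ([categorical_regression()]), and extracts outlier features
#' along each layer's selected components ([select_features()]).  Class
#' labels enter only the validation step, never the selection itself.
#'
#' @param layers named list of [omics_matrix()] objects (names default to
#'   each matrix's layer tag).
#' @param design a [sample_design()] covering the shared samples.
#' @param center centering mode passed to [pca_decompose()].
#' @param log2 if `TRUE`, log2-transform each layer before decomposition
#'   (for linear-scale intensities/abundances).
#' @param cut_height,min_layers,max_k passed to [select_pcs()].
#' @param method,alpha,robust passed to [selection_criterion()]; each layer
#'   is tested along its selected component indices (at most the two
#'   lowest-index selected components per layer).  Set `robust = TRUE` when
#'   a sizeable fraction of a layer's features is expected to be outlying
#'   (see the methods vignette).
#' @return an object of class `pcaufe`: list with elements `decompositions`
#'   (per layer), `tree` ([build_pc_tree()]), `selected` ([select_pcs()]),
#'   `fits` (per selected component, [categorical_regression()]),
#'   `correlations` ([scatter_report()] table), `selections` (per layer
#'   with a selected component, [select_features()]), `design`, and `call`.
#' @examples
#' ds <- simulate_multiomics(synthetic_config(
#'   n_features = c(compound = 60, mRNA = 120, miRNA = 50),
#'   n_planted_tumor = c(compound = 5, mRNA = 8, miRNA = 4),
#'   n_planted_icc = c(compound = 5, mRNA = 8, miRNA = 4)))
#' fit <- pcaufe(ds$layers, ds$design, log2 = TRUE)
#' print(fit)
#' @export
pcaufe <- function(layers, design,
                   center = c("feature_mean", "none"),
                   log2 = FALSE,
                   cut_height = 0.6, min_layers = 2L, max_k = NULL,
                   method = c("chi2_bh", "score_quantile"), alpha = 0.01,
                   robust = FALSE) {
  center <- match.arg(center)
  method <- match.arg(method)
  stopifnot(is.list(layers), length(layers) >= 1L)
  layers <- align_layers(layers, design)
  if (log2) {
    layers <- lapply(layers, function(m) {
      if (any(m <= 0)) abort("log2 transform requires strictly positive values")
      omics_matrix(log2(unclass(m)), omics_layer(m),
                   symbols = feature_symbols(m))
    })
  }
  names(layers) <- vapply(layers, omics_layer, "")
  decomps <- lapply(layers, pca_decompose, center = center)

  tree <- build_pc_tree(decomps)
  selected <- select_pcs(tree, cut_height = cut_height,
                         min_layers = min_layers, max_k = max_k)
  fits <- lapply(seq_len(nrow(selected$members)), function(i) {
    categorical_regression(decomps[[selected$members$layer[i]]],
                           selected$members$k[i], design)
  })
  names(fits) <- selected$members$label
  correlations <- scatter_report(selected, decomps)

  selections <- list()
  for (ly in unique(selected$members$layer)) {
    axes <- sort(selected$members$k[selected$members$layer == ly])
    if (length(axes) > 2L) axes <- axes[1:2]
    crit <- selection_criterion(ly, axes, method = method, alpha = alpha,
                                robust = robust)
    selections[[ly]] <- select_features(decomps[[ly]], crit)
  }

  structure(list(decompositions = decomps,
                 tree = tree,
                 selected = selected,
                 fits = fits,
                 correlations = correlations,
                 selections = selections,
                 design = design,
                 center = center,
                 log2 = log2,
                 call = match.call()),
            class = "pcaufe")
}

#' @export
print.pcaufe <- function(x, ...) {
  cat("Integrated multi-omics component analysis\n")
  cat(sprintf("layers: %s; %d samples\n",
              paste(names(x$decompositions), collapse = ", "),
              nrow(x$design)))
  cat(sprintf("selected components (cut %.2f, mean |r| = %.3f): %s\n",
              x$selected$cut_height, x$selected$cluster_mean_abs_r,
              paste(x$selected$members$label, collapse = ", ")))
  for (ly in names(x$selections)) {
    cat(sprintf("  %s: %d outlier features\n", ly,
                length(x$selections[[ly]]$selected)))
  }
  invisible(x)
}

#' @export
summary.pcaufe <- function(object, ...) {
  fits <- data.frame(
    pc = names(object$fits),
    F_statistic = vapply(object$fits, `[[`, 0, "F_statistic"),
    p_value = vapply(object$fits, `[[`, 0, "p_value"),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(selected = object$selected,
              fits = fits,
              correlations = object$correlations,
              n_selected_features = vapply(object$selections, function(s)
                length(s$selected), 0L))
  class(out) <- "summary.pcaufe"
  out
}

#' @export
print.summary.pcaufe <- function(x, ...) {
  print(x$selected)
  cat("\ncategorical regression of selected components:\n")
  print(transform(x$fits,
                  F_statistic = signif(F_statistic, 4),
                  p_value = signif(p_value, 3)))
  cat("\noutlier features per layer:\n")
  print(x$n_selected_features)
  invisible(x)
}

#' Plot an integrated analysis
#'
#' `which = "tree"` draws the UPGMA dendrogram of pooled components with
#' the selected cluster highlighted; `which = "embedding"` draws, for one
#' layer, the feature embedding along the layer's selected component axes
#' (or axis vs rank when only one is selected) with selected outlier
#' features marked.
#'
#' @param x a [pcaufe()] result.
#' @param which `"tree"` or `"embedding"`.
#' @param layer layer name for `which = "embedding"` (default: first layer
#'   with a selection).
#' @param ... passed to the underlying plot function.
#' @return `x`, invisibly.
#' @export
plot.pcaufe <- function(x, which = c("tree", "embedding"), layer = NULL, ...) {
  which <- match.arg(which)
  if (which == "tree") {
    hc <- x$tree$hclust
    plot(hc, hang = -1, cex = 0.6, xlab = "", sub = "",
         ylab = "1 - |r|", main = "UPGMA of pooled components", ...)
    sel <- x$selected$members$label
    labs <- hc$labels[hc$order]
    mtext(side = 1, at = which(labs %in% sel), text = "*", col = 2, line = 2)
  } else {
    layer <- layer %||% names(x$selections)[1L]
    sel <- x$selections[[layer]]
    if (is.null(sel)) abort("no selection for layer '%s'", layer)
    d <- x$decompositions[[layer]]
    axes <- sel$criterion$axes
    if (length(axes) == 2L) {
      e <- embed2d(d, axes[1L], axes[2L])
      xy <- cbind(e$x, e$y)
      xl <- paste0("PC", axes[1L]); yl <- paste0("PC", axes[2L])
    } else {
      xy <- cbind(seq_along(d$feature_ids), d$feature_scores[, axes])
      xl <- "feature rank"; yl <- paste0("PC", axes)
    }
    hit <- d$feature_ids %in% sel$selected
    plot(xy, col = ifelse(hit, 2, 1), pch = ifelse(hit, 19, 1),
         xlab = xl, ylab = yl,
         main = sprintf("%s: %d outliers", layer, sum(hit)), ...)
  }
  invisible(x)
}
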