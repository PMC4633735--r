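#' Criterion for PCA-based unsupervised outlier feature selection
#'
#' Specifies which component axes of a layer's decomposition are tested and
#' how outliers along them are thresholded.  Class labels play no role in
#' the selection: features are flagged purely for having outlying scores
#' along the chosen components (e.g. compounds along PC3, mRNA along PC1,
#' miRNA along PC1 and PC2).
#'
#' @param layer layer name the criterion applies to.
#' @param axes one or two 1-based component indices.
#' @param method `"chi2_bh"` (default): squared standardized scores summed
#'   over the axes are referred to a chi-squared distribution with one
#'   degree of freedom per axis, p-values are Benjamini-Hochberg adjusted
#'   across the layer's features, and features with adjusted p below
#'   `alpha` are selected.  `"score_quantile"`: select features whose
#'   statistic exceeds the `quantile` quantile of the layer's statistics.
#' @param alpha adjusted-significance threshold for `chi2_bh`.
#' @param quantile probability threshold for `score_quantile`.
#' @param robust if `TRUE`, standardize axis scores by the median absolute
#'   deviation instead of the standard deviation (guards heavy-tailed score
#'   distributions; the chi-squared null then holds only approximately).
#' @return an object of class `selection_criterion`.
#' @export
selection_criterion <- function(layer, axes,
                                method = c("chi2_bh", "score_quantile"),
                                alpha = 0.01, quantile = 0.99,
                                robust = FALSE) {
  method <- match.arg(method)
  axes <- as.integer(axes)
  if (length(axes) < 1L || length(axes) > 2L) abort("1 or 2 axes required")
  if (any(axes < 1L)) abort("axes must be >= 1")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0,1)")
  if (!(quantile > 0 && quantile < 1)) abort("quantile must be in (0,1)")
  structure(list(layer = layer, axes = axes, method = method,
                 alpha = alpha, quantile = quantile, robust = robust),
            class = "selection_criterion")
}

#' Select outlier features along chosen components
#'
#' Each feature's score on each criterion axis is standardized by the
#' across-feature spread of that axis; the feature's statistic is the sum
#' of squared standardized scores over the axes.  Under the null of no
#' signal the statistic is approximately chi-squared with one degree of
#' freedom per axis, so the default `chi2_bh` method converts it to an
#' upper-tail p-value, adjusts across the layer's features by
#' Benjamini-Hochberg, and selects adjusted p < alpha.  An empty selection
#' is a legitimate outcome, not an error.
#'
#' @param d a [pca_decompose()] result.
#' @param crit a [selection_criterion()] for `d`'s layer.
#' @return an object of class `feature_selection`: list with `layer`,
#'   `selected` (feature identifiers ordered by decreasing statistic),
#'   `table` (data frame `feature_id`, `statistic`, `p_value`,
#'   `p_adjusted` in input feature order; p columns are NA for the
#'   `score_quantile` method), `criterion`.
#' @export
select_features <- function(d, crit) {
  stopifnot(inherits(d, "pc_decomposition"), inherits(crit, "selection_criterion"))
  if (any(crit$axes > d$n_components)) {
    abort("criterion axes out of range (1..%d)", d$n_components)
  }
  sc <- d$feature_scores[, crit$axes, drop = FALSE]
  spread <- apply(sc, 2L, if (crit$robust) stats::mad else stats::sd)
  if (any(spread <= 0 | !is.finite(spread))) {
    abort("zero spread along axis %s",
          .listing(crit$axes[spread <= 0 | !is.finite(spread)]))
  }
  z <- sweep(sc, 2L, spread, `/`)
  stat <- rowSums(z^2)
  if (crit$method == "chi2_bh") {
    p <- stats::pchisq(stat, df = length(crit$axes), lower.tail = FALSE)
    padj <- stats::p.adjust(p, method = "BH")
    sel <- which(padj < crit$alpha)
  } else {
    thr <- stats::quantile(stat, probs = crit$quantile, names = FALSE)
    p <- rep(NA_real_, length(stat))
    padj <- p
    sel <- which(stat > thr)
  }
  sel <- sel[order(stat[sel], decreasing = TRUE)]
  structure(list(layer = d$layer,
                 selected = d$feature_ids[sel],
                 table = data.frame(feature_id = d$feature_ids,
                                    statistic = stat,
                                    p_value = p,
                                    p_adjusted = padj,
                                    stringsAsFactors = FALSE),
                 criterion = crit),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection [%s]: %d of %d features selected (%s on PC %s)\n",
              x$layer, length(x$selected), nrow(x$table),
              x$criterion$method, paste(x$criterion$axes, collapse = ",")))
  if (length(x$selected)) cat("top:", .listing(x$selected, 8), "\n")
  invisible(x)
}

#' Collapse probe-level selections to symbols
#'
#' Microarrays carry multiple probes per gene; a probe-level selection is
#' collapsed to a de-duplicated symbol list preserving first-occurrence
#' order, retaining per-symbol probe counts.  Features without a mapping
#' pass through under their own identifier.
#'
#' @param sel a [select_features()] result.
#' @param mapping named character vector, feature identifier -> symbol.
#' @return data frame with columns `symbol`, `n_probes`, `probes`
#'   (comma-separated probe identifiers).
#' @export
collapse_probes <- function(sel, mapping) {
  stopifnot(inherits(sel, "feature_selection"))
  probes <- sel$selected
  if (length(probes) == 0L) {
    return(data.frame(symbol = character(), n_probes = integer(),
                      probes = character(), stringsAsFactors = FALSE))
  }
  sym <- unname(mapping[probes])
  sym[is.na(sym)] <- probes[is.na(sym)]
  first <- !duplicated(sym)
  out <- data.frame(symbol = sym[first], stringsAsFactors = FALSE)
  out$n_probes <- as.integer(table(sym)[out$symbol])
  out$probes <- vapply(out$symbol, function(s)
    paste(probes[sym == s], collapse = ","), "")
  rownames(out) <- NULL
  out
}

#' Class-pattern summary of selected features
#'
#' For each selected feature, the per-class means and a pattern call
#' deciding which of the study's two planned contrasts dominates:
#' `tumor_vs_nontumor` (ICC + HCC vs the non-tumor classes) or
#' `icc_vs_rest` (ICC vs the other three classes), whichever has the larger
#' standardized effect (|difference of group means| / pooled within-group
#' standard deviation).  Features with no variation get zero effects and
#' the call `mixed`.
#'
#' @param sel a [select_features()] result.
#' @param m the layer's [omics_matrix()].
#' @param design a [sample_design()] covering `m`'s samples.
#' @return data frame with one row per selected feature: `feature_id`, one
#'   mean column per class, `effect_tumor`, `effect_icc`, `pattern`.
#' @export
pattern_table <- function(sel, m, design) {
  stopifnot(inherits(sel, "feature_selection"), inherits(m, "omics_matrix"),
            inherits(design, "sample_design"))
  missing_f <- setdiff(sel$selected, rownames(m))
  if (length(missing_f)) abort("selected features missing from matrix: %s",
                               .listing(missing_f))
  .check_design_matches(design, colnames(m))
  cls <- design$class[match(colnames(m), design$sample_id)]
  tumor <- cls %in% c("ICC", "HCC")
  icc <- cls == "ICC"
  rows <- lapply(sel$selected, function(f) {
    v <- as.numeric(m[f, ])
    mu <- tapply(v, cls, mean)[levels(cls)]
    e_t <- .std_effect(v, tumor)
    e_i <- .std_effect(v, icc)
    pattern <- if (abs(e_t - e_i) < 1e-12) "mixed"
               else if (e_t > e_i) "tumor_vs_nontumor" else "icc_vs_rest"
    cbind(data.frame(feature_id = f, stringsAsFactors = FALSE),
          as.data.frame(as.list(mu)),
          data.frame(effect_tumor = e_t, effect_icc = e_i, pattern = pattern,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# standardized two-group effect: |mean1 - mean2| / pooled within-group sd
.std_effect <- function(v, grp1) {
  a <- v[grp1]; b <- v[!grp1]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) return(0)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  dm <- abs(mean(a) - mean(b))
  if (sp2 <= 0) {
    if (dm == 0) 0 else Inf
  } else {
    dm / sqrt(sp2)
  }
}
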