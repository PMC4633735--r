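#' Three-class diagnostic task specification
#'
#' Collapses the four design classes onto the three diagnostic labels used
#' for reporting — `non-tumor` (both surrounding-tissue groups pooled),
#' `HCC`, and `ICC` — and fixes the feature panel and classifier for
#' leave-one-out cross-validation.
#'
#' @param panel non-empty character vector of feature identifiers.
#' @param classifier `"lda"` (linear discriminant analysis with equal
#'   priors; the conventional choice for small-cohort microarray LOOCV) or
#'   `"nearest_centroid"` (Euclidean distance to class centroids in the
#'   standardized feature space).
#' @param class_map named character vector mapping every design class to a
#'   diagnostic label.
#' @param labels diagnostic label order used in reports.
#' @param log2 if `TRUE`, log2-transform the panel values before
#'   classification (use for linear-scale intensities).
#' @param standardize if `TRUE` (default), center and scale each panel
#'   feature using training-fold statistics only, so no information from
#'   the held-out sample leaks into the model.
#' @return an object of class `diagnostic_task`.
#' @export
diagnostic_task <- function(panel,
                            classifier = c("lda", "nearest_centroid"),
                            class_map = c(ICC = "ICC", ICC_NT = "non-tumor",
                                          HCC = "HCC", HCC_NT = "non-tumor"),
                            labels = c("non-tumor", "HCC", "ICC"),
                            log2 = FALSE,
                            standardize = TRUE) {
  classifier <- match.arg(classifier)
  panel <- as.character(panel)
  if (length(panel) == 0L) abort("panel must be non-empty")
  if (is.null(names(class_map))) abort("class_map must be named by design class")
  if (!all(class_map %in% labels)) {
    abort("class_map values must be diagnostic labels (%s)",
          paste(labels, collapse = ", "))
  }
  structure(list(panel = panel, classifier = classifier,
                 class_map = class_map, labels = labels,
                 log2 = log2, standardize = standardize),
            class = "diagnostic_task")
}

#' Leave-one-out cross-validated diagnosis
#'
#' Each sample in turn is held out; the classifier is trained on the
#' remaining samples restricted to the panel features (optionally
#' log-transformed, standardized with training-fold statistics only) and
#' predicts the held-out sample's diagnostic label.  Predictions are
#' aggregated into a 3 x 3 confusion matrix (rows = predicted, columns =
#' true) and an overall accuracy.
#'
#' Training folds with singular within-class structure make plain LDA
#' unusable; in that event the fold falls back to a diagonal-covariance
#' discriminant (a regularized variant) and the fallback is recorded in the
#' report's `notes`.  Features constant within a training fold are dropped
#' for that fold; if none remain the fold predicts the majority training
#' label (ties broken by label order).
#'
#' @param m an [omics_matrix()] containing the panel features.
#' @param design a [sample_design()] covering `m`'s samples.
#' @param task a [diagnostic_task()].
#' @return an object of class `classification_report`: list with
#'   `predictions` (data frame `sample_id`, `true`, `predicted`),
#'   `confusion` (3 x 3 count matrix, rows = predicted), `accuracy_percent`
#'   (half-up rounded to 2 decimals; unrounded value in attribute
#'   `"exact"`), `task`, `notes`.
#' @examples
#' ds <- simulate_multiomics(synthetic_config(
#'   n_features = c(compound = 40, mRNA = 60, miRNA = 30),
#'   n_planted_tumor = c(compound = 6, mRNA = 6, miRNA = 3),
#'   n_planted_icc = c(compound = 6, mRNA = 6, miRNA = 3),
#'   effect_size_tumor = 4, effect_size_icc = 4))
#' panel <- unlist(ds$truth$compound)
#' rep <- loocv_diagnose(ds$layers$compound, ds$design,
#'                       diagnostic_task(panel, log2 = TRUE))
#' rep$confusion
#' @export
loocv_diagnose <- function(m, design, task) {
  stopifnot(inherits(m, "omics_matrix"), inherits(design, "sample_design"),
            inherits(task, "diagnostic_task"))
  .check_design_matches(design, colnames(m))
  missing_f <- setdiff(task$panel, rownames(m))
  if (length(missing_f)) abort("panel features missing from matrix: %s",
                               .listing(missing_f))
  unknown_cls <- setdiff(levels(droplevels(design$class)), names(task$class_map))
  if (length(unknown_cls)) abort("class_map does not cover: %s",
                                 .listing(unknown_cls))

  sample_ids <- design$sample_id          # canonical order: design order
  x <- t(m[task$panel, sample_ids, drop = FALSE])
  storage.mode(x) <- "double"
  if (task$log2) {
    if (any(x <= 0)) abort("log2 transform requires strictly positive values")
    x <- log2(x)
  }
  y <- factor(unname(task$class_map[as.character(design$class)]),
              levels = task$labels)
  tab <- table(y)
  if (any(tab < 2L)) {
    abort("need >= 2 samples per diagnostic label (got %s)",
          paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  }

  notes <- character()
  preds <- factor(rep(NA_character_, length(y)), levels = task$labels)
  for (i in seq_along(y)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y)) {
      abort("training fold for sample '%s' loses an entire class", sample_ids[i])
    }
    xte <- x[i, , drop = FALSE]
    keep <- apply(xtr, 2L, function(v) stats::sd(v) > 0)
    if (!any(keep)) {
      # no informative features: majority training label, ties by label order
      preds[i] <- names(which.max(table(ytr)))
      notes <- c(notes, sprintf("sample %s: no non-constant panel features; majority vote",
                                sample_ids[i]))
      next
    }
    xtr <- xtr[, keep, drop = FALSE]
    xte <- xte[, keep, drop = FALSE]
    if (task$standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      xtr <- scale(xtr, center = mu, scale = sdv)
      xte <- scale(xte, center = mu, scale = sdv)
    }
    preds[i] <- switch(task$classifier,
      lda = {
        fit <- tryCatch(
          suppressWarnings(MASS::lda(xtr, grouping = ytr,
                                     prior = rep(1 / nlevels(ytr), nlevels(ytr)))),
          error = function(e) NULL)
        if (is.null(fit)) {
          notes <- c(notes, sprintf("sample %s: singular LDA; diagonal-covariance fallback",
                                    sample_ids[i]))
          .diag_discriminant(xtr, ytr, xte)
        } else {
          as.character(stats::predict(fit, xte)$class)
        }
      },
      nearest_centroid = .nearest_centroid(xtr, ytr, xte)
    )
  }

  predictions <- data.frame(sample_id = sample_ids,
                            true = as.character(y),
                            predicted = as.character(preds),
                            stringsAsFactors = FALSE)
  confusion <- table(predicted = preds, true = y)
  confusion <- unclass(confusion)[task$labels, task$labels]
  acc <- accuracy_from_confusion(confusion)
  structure(list(predictions = predictions,
                 confusion = confusion,
                 accuracy_percent = acc,
                 task = task,
                 notes = notes),
            class = "classification_report")
}

# nearest centroid with deterministic tie-breaking: larger training class
# first, then label order
.nearest_centroid <- function(xtr, ytr, xte) {
  lv <- levels(ytr)
  cent <- t(vapply(lv, function(l) colMeans(xtr[ytr == l, , drop = FALSE]),
                   numeric(ncol(xtr))))
  dists <- apply(cent, 1L, function(cc) sqrt(sum((xte - cc)^2)))
  best <- which(dists <= min(dists) + 1e-12)
  if (length(best) > 1L) {
    sizes <- table(ytr)[lv[best]]
    best <- best[order(-as.integer(sizes), best)][1L]
  }
  lv[best]
}

# diagonal-covariance Gaussian discriminant (equal priors): regularized
# stand-in when pooled-covariance LDA is singular
.diag_discriminant <- function(xtr, ytr, xte) {
  lv <- levels(ytr)
  v <- apply(xtr, 2L, stats::var)
  v[v <= 0] <- max(v[v > 0], 1)      # guard exactly-constant columns
  scores <- vapply(lv, function(l) {
    mu <- colMeans(xtr[ytr == l, , drop = FALSE])
    -sum((xte - mu)^2 / v)
  }, 0)
  lv[which.max(scores)]
}

#' Overall accuracy from a confusion matrix
#'
#' 100 x (sum of the diagonal) / (sum of all entries), rounded half-up to
#' two decimals for display (e.g. 27/32 -> 84.38, 25/32 -> 78.13); the
#' unrounded value is retained in the `"exact"` attribute.
#'
#' @param confusion square count matrix (rows = predicted, columns = true).
#' @return accuracy in percent (rounded to 2 decimals), with attribute
#'   `"exact"` holding the unrounded value.
#' @examples
#' cm <- matrix(c(14, 0, 2, 0, 5, 1, 2, 0, 8), 3, 3)
#' accuracy_from_confusion(cm)  # 84.38
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) abort("confusion matrix must be square")
  if (any(confusion < 0)) abort("negative counts")
  total <- sum(confusion)
  if (total == 0) abort("empty confusion matrix")
  exact <- 100 * sum(diag(confusion)) / total
  structure(round_half_up(exact, 2), exact = exact)
}

#' Per-label sensitivity and specificity
#'
#' One-vs-rest sensitivity (recall of the label's true instances) and
#' specificity (recall of the non-instances) per diagnostic label, computed
#' from the confusion matrix.  A label with zero true instances has
#' undefined sensitivity, reported as `NA` rather than 0.
#'
#' @param report a [loocv_diagnose()] result, or a square confusion matrix
#'   (rows = predicted, columns = true).
#' @return data frame with columns `label`, `sensitivity`, `specificity`.
#' @export
per_class_metrics <- function(report) {
  confusion <- if (inherits(report, "classification_report"))
    report$confusion else as.matrix(report)
  if (nrow(confusion) != ncol(confusion)) abort("confusion matrix must be square")
  total <- sum(confusion)
  labels <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  out <- lapply(seq_len(nrow(confusion)), function(l) {
    tp <- confusion[l, l]
    col <- sum(confusion[, l])        # true instances
    row <- sum(confusion[l, ])        # predicted instances
    tn <- total - col - row + tp
    data.frame(label = labels[l],
               sensitivity = if (col == 0) NA_real_ else tp / col,
               specificity = if (total - col == 0) NA_real_ else tn / (total - col),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: LOOCV %s on %d-feature panel\n",
              x$task$classifier, length(x$task$panel)))
  cat("confusion (rows = predicted, columns = true):\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.2f%%\n", x$accuracy_percent))
  if (length(x$notes)) cat("notes:", length(x$notes), "fold note(s)\n")
  invisible(x)
}

#' Write a classification report to a run directory
#'
#' Emits the confusion matrix (rows = predicted) and per-sample predictions
#' as delimited text.
#'
#' @param report a [loocv_diagnose()] result.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_classification_report <- function(report, dir, sep = "\t") {
  stopifnot(inherits(report, "classification_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- data.frame(predicted = rownames(report$confusion),
                     report$confusion, check.names = FALSE)
  utils::write.table(conf, file.path(dir, "confusion.tsv"), sep = sep,
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$predictions, file.path(dir, "predictions.tsv"),
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(dir)
}
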