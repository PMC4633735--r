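test_that("confusion-matrix accuracy uses half-up rounding to two decimals", {
  perfect <- diag(c(5, 5, 5))
  expect_equal(as.numeric(accuracy_from_confusion(perfect)), 100)
  cm <- matrix(c(6, 1, 1, 0, 7, 1, 0, 0, 0), 3, 3)   # 13/16 = 81.25
  expect_equal(as.numeric(accuracy_from_confusion(cm)), 81.25)
  # 25/32 = 78.125 must round up, not to even
  cm2 <- diag(c(13, 4, 8)); cm2[1, 2] <- 7
  expect_equal(as.numeric(accuracy_from_confusion(cm2)), 78.13)
  expect_equal(attr(accuracy_from_confusion(cm2), "exact"), 100 * 25 / 32)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
  expect_error(accuracy_from_confusion(matrix(-1, 2, 2)), "negative")
  expect_error(accuracy_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("per-class metrics handle perfect, degenerate and empty labels", {
  labels <- c("non-tumor", "HCC", "ICC")
  perfect <- diag(c(16, 6, 10))
  dimnames(perfect) <- list(labels, labels)
  pm <- per_class_metrics(perfect)
  expect_true(all(pm$sensitivity == 1) && all(pm$specificity == 1))

  # everything predicted as one class
  one <- matrix(0, 3, 3, dimnames = list(labels, labels))
  one[1, ] <- c(16, 6, 10)
  pm1 <- per_class_metrics(one)
  expect_identical(pm1$specificity[1], 0)
  expect_identical(pm1$sensitivity[2:3], c(0, 0))

  # a label with zero true instances is undefined, not zero
  z <- matrix(c(5, 0, 0, 3, 0, 0, 0, 0, 0), 3, 3, dimnames = list(labels, labels))
  expect_true(is.na(per_class_metrics(z)$sensitivity[3]))
})

test_that("LOOCV separates strongly planted panels almost perfectly", {
  ds <- simulate_multiomics(small_config(
    seed = 41, effect_size_tumor = 4, effect_size_icc = 4))
  panel <- c(ds$truth$compound$tumor, ds$truth$compound$icc)
  for (clf in c("lda", "nearest_centroid")) {
    rep <- loocv_diagnose(ds$layers$compound, ds$design,
                          diagnostic_task(panel, classifier = clf, log2 = TRUE))
    expect_gte(as.numeric(rep$accuracy_percent), 95)
    # confusion totals conserve the per-label sample counts
    expect_identical(unname(colSums(rep$confusion)), c(16, 6, 10))
    expect_identical(sum(rep$confusion), 32L)
    # accuracy equals trace/total exactly
    expect_equal(attr(rep$accuracy_percent, "exact"),
                 100 * sum(diag(rep$confusion)) / 32)
  }
})

test_that("a constant panel predicts the majority class", {
  ds <- simulate_multiomics(small_config(seed = 42))
  vals <- unclass(ds$layers$compound)
  vals["compound_0001", ] <- 7
  m <- omics_matrix(vals, "compound")
  rep <- loocv_diagnose(m, ds$design, diagnostic_task("compound_0001"))
  # majority label is non-tumor (16/32): every prediction falls there
  expect_true(all(rep$predictions$predicted == "non-tumor"))
  expect_equal(as.numeric(rep$accuracy_percent), 50)
  expect_gt(length(rep$notes), 0)
})

test_that("LOOCV predictions are invariant to sample ordering", {
  ds <- simulate_multiomics(small_config(seed = 43))
  panel <- c(ds$truth$compound$tumor, ds$truth$compound$icc)
  task <- diagnostic_task(panel, log2 = TRUE)
  r1 <- loocv_diagnose(ds$layers$compound, ds$design, task)
  set.seed(1)
  perm <- sample(nrow(ds$design))
  design2 <- sample_design(ds$design$sample_id[perm],
                           as.character(ds$design$class)[perm])
  r2 <- loocv_diagnose(ds$layers$compound, design2, task)
  p1 <- r1$predictions[order(r1$predictions$sample_id), ]
  p2 <- r2$predictions[order(r2$predictions$sample_id), ]
  expect_identical(p1$predicted, p2$predicted)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("permuted labels drive LOOCV accuracy to the chance band", {
  ds <- simulate_multiomics(small_config(seed = 44, effect_size_tumor = 3,
                                         effect_size_icc = 3))
  panel <- c(ds$truth$compound$tumor, ds$truth$compound$icc)
  set.seed(2)
  accs <- vapply(1:10, function(i) {
    perm_design <- sample_design(ds$design$sample_id,
                                 sample(as.character(ds$design$class)))
    r <- loocv_diagnose(ds$layers$compound, perm_design,
                        diagnostic_task(panel, classifier = "nearest_centroid",
                                        log2 = TRUE))
    attr(r$accuracy_percent, "exact")
  }, 0)
  # with three labels at 16/6/10 of 32, chance is far below the planted 95+
  expect_lt(mean(accs), 70)
})

test_that("task validation catches bad panels and class maps", {
  ds <- simulate_multiomics(small_config(seed = 45))
  expect_error(diagnostic_task(character()), "non-empty")
  expect_error(loocv_diagnose(ds$layers$compound, ds$design,
                              diagnostic_task("not_a_feature")), "missing")
  expect_error(diagnostic_task("f1", class_map = c(ICC = "banana")),
               "diagnostic labels")
})

test_that("reports write a Table-1 oriented confusion matrix", {
  ds <- simulate_multiomics(small_config(seed = 46))
  panel <- c(ds$truth$compound$tumor, ds$truth$compound$icc)
  rep <- loocv_diagnose(ds$layers$compound, ds$design,
                        diagnostic_task(panel, log2 = TRUE))
  dir <- withr::local_tempdir()
  write_classification_report(rep, dir)
  conf <- read.delim(file.path(dir, "confusion.tsv"), check.names = FALSE)
  expect_identical(conf$predicted, rownames(rep$confusion))
  expect_identical(unname(as.matrix(conf[, -1])), unname(rep$confusion))
})

test_that("reference confusion matrices reproduce the cohort arithmetic", {
  ref <- gse57555_reference()
  expect_identical(sum(ref$confusion_compound), 32)
  expect_identical(sum(ref$confusion_mirna), 32)
  pm <- per_class_metrics(ref$confusion_compound)
  expect_equal(pm$sensitivity[pm$label == "ICC"], 8 / 10)
})
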