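#' Reference results for the GSE57555 liver-cancer cohort
#'
#' Documented expected outputs of the pipeline on the original cohort of
#' 10 intrahepatic cholangiocarcinoma (ICC) and 6 hepatocellular carcinoma
#' (HCC) patients with matched surrounding non-tumor tissue (32 samples;
#' mRNA and miRNA arrays deposited as GEO series GSE57555, metabolome
#' profiled by CE-TOFMS).  Reproducing them end-to-end requires the
#' deposited array data plus the study's unreleased metabolite table, so
#' they are shipped as reference values rather than recomputed:
#'
#' \describe{
#'   \item{confusion_compound}{3 x 3 LOOCV confusion matrix of the
#'     14-compound panel (rows = predicted, columns = true); 27/32 correct,
#'     84.38\% accuracy.}
#'   \item{confusion_mirna}{3 x 3 LOOCV confusion matrix of the 17-miRNA
#'     panel; 25/32 correct, 78.13\% accuracy.}
#'   \item{selected_pcs}{the five cross-layer components the correlation
#'     clustering selects.}
#'   \item{categorical_p}{categorical-regression p-values of those five
#'     components.}
#'   \item{selection_counts}{outlying features per layer (62 mRNAs arise
#'     from 67 probes).}
#'   \item{design_counts}{samples per design class.}
#' }
#'
#' The confusion matrices are fully recomputable arithmetic inputs:
#' [accuracy_from_confusion()] and [per_class_metrics()] applied to them
#' reproduce the cohort's headline diagnostic numbers.
#'
#' @return a named list as described above.
#' @examples
#' ref <- gse57555_reference()
#' accuracy_from_confusion(ref$confusion_compound)  # 84.38
#' @export
gse57555_reference <- function() {
  labels <- c("non-tumor", "HCC", "ICC")
  conf_comp <- matrix(c(14, 0, 2,
                         0, 5, 0,
                         2, 1, 8),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(predicted = labels, true = labels))
  conf_mirna <- matrix(c(13, 1, 1,
                          2, 4, 1,
                          1, 1, 8),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(predicted = labels, true = labels))
  list(
    accession = "GSE57555",
    design_counts = c(ICC = 10L, ICC_NT = 10L, HCC = 6L, HCC_NT = 6L),
    confusion_compound = conf_comp,
    confusion_mirna = conf_mirna,
    selected_pcs = c("PC3_compound", "PC1_mRNA", "PC2_mRNA",
                     "PC1_miRNA", "PC2_miRNA"),
    categorical_p = c(PC3_compound = 8.68e-03, PC1_mRNA = 1.69e-02,
                      PC2_mRNA = 3.98e-06, PC1_miRNA = 4.74e-02,
                      PC2_miRNA = 9.42e-03),
    selection_counts = c(compound = 14L, mRNA = 62L, mRNA_probes = 67L,
                         miRNA = 17L)
  )
}
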