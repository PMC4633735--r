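Package: pcaufe
Title: Multi-Omics Integration by Principal Component Correlation
    Clustering and PCA-Based Unsupervised Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of matched transcriptome (mRNA, miRNA) and
    metabolome (compound) profiles measured on the same samples.  Each omics
    layer is decomposed by feature-space principal component analysis, in
    which every feature is a point in sample space and each component carries
    a per-sample contribution vector.  Contribution vectors from all layers
    are pooled and clustered by UPGMA on the correlation distance 1 - |r| to
    find coherent cross-layer components; class separation along each
    selected component is validated by categorical regression (one-way
    ANOVA on class indicators).  Outlying features along the selected
    components are extracted without using class labels (chi-squared test on
    standardized component scores with Benjamini-Hochberg control), and a
    selected feature panel drives a leave-one-out cross-validated three-class
    diagnosis with confusion-matrix reporting.  Includes a synthetic
    multi-layer data generator with planted class-contrast features for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
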