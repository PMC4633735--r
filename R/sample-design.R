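#' Sample design: assignment of samples to classes
#'
#' Maps each sample to exactly one class.  The default class vocabulary is
#' the four-group liver cohort layout: `ICC` and `HCC` tumors with their
#' matched surrounding non-tumor tissues `ICC_NT` and `HCC_NT`.  The design
#' provides the class indicator \eqn{\delta_{a,i}} (1 if sample *i* belongs
#' to class *a*, else 0) used by [categorical_regression()]; each sample's
#' indicators sum to one.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param class character vector (same length) of class labels.
#' @param classes the allowed class vocabulary, in display order.
#' @return a data frame of class `sample_design` with columns `sample_id`
#'   and `class` (factor over `classes`).
#' @examples
#' d <- sample_design(c("s1", "s2", "s3", "s4"),
#'                    c("ICC", "ICC_NT", "HCC", "HCC_NT"))
#' design_indicator(d)
#' @export
sample_design <- function(sample_id, class,
                          classes = c("ICC", "ICC_NT", "HCC", "HCC_NT")) {
  sample_id <- as.character(sample_id)
  class <- as.character(class)
  if (length(sample_id) != length(class)) abort("sample_id and class lengths differ")
  if (length(sample_id) == 0L) abort("empty design")
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) abort("duplicate samples in design: %s", .listing(dup))
  unknown <- setdiff(unique(class), classes)
  if (length(unknown)) {
    abort("unknown class label(s): %s (allowed: %s)",
          .listing(unknown), paste(classes, collapse = ", "))
  }
  structure(
    data.frame(sample_id = sample_id,
               class = factor(class, levels = classes),
               stringsAsFactors = FALSE),
    class = c("sample_design", "data.frame")
  )
}

#' @rdname sample_design
#' @param design a `sample_design`.
#' @return `design_indicator()`: the n-samples x n-classes 0/1 indicator
#'   matrix \eqn{\delta_{a,i}}; every row sums to 1.
#' @export
design_indicator <- function(design) {
  stopifnot(inherits(design, "sample_design"))
  lv <- levels(design$class)
  delta <- vapply(lv, function(a) as.integer(design$class == a),
                  integer(nrow(design)))
  rownames(delta) <- design$sample_id
  delta
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d samples in %d classes\n",
              nrow(x), nlevels(x$class)))
  print(table(x$class))
  invisible(x)
}

#' Read a sample design from a two-column delimited file
#'
#' Expects a header and two columns, `sample_id` and `class`.
#'
#' @inheritParams sample_design
#' @param path file path.
#' @param sep field separator.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path, sep = "\t",
                               classes = c("ICC", "ICC_NT", "HCC", "HCC_NT")) {
  if (!file.exists(path)) abort("no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("design file %s needs two columns (sample_id, class)", path)
  sample_design(df[[1L]], df[[2L]], classes = classes)
}

#' @rdname read_sample_design
#' @param design a [sample_design()] to write.
#' @export
write_sample_design <- function(design, path, sep = "\t") {
  stopifnot(inherits(design, "sample_design"))
  out <- data.frame(sample_id = design$sample_id,
                    class = as.character(design$class))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check a design covers exactly the samples of a matrix; used by loocv etc.
.check_design_matches <- function(design, sample_ids) {
  missing_d <- setdiff(sample_ids, design$sample_id)
  extra_d <- setdiff(design$sample_id, sample_ids)
  if (length(missing_d) || length(extra_d)) {
    abort("design/sample mismatch: samples without class [%s]; classes without sample [%s]",
          .listing(missing_d), .listing(extra_d))
  }
  invisible(TRUE)
}
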