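#' Construct an omics data matrix
#'
#' An `omics_matrix` is one layer's feature-by-sample value table: a numeric
#' matrix with unique feature identifiers as row names, unique sample
#' identifiers as column names, a layer tag (`"compound"`, `"mRNA"`,
#' `"miRNA"`, or any other name), and an optional feature-to-symbol map.
#' Values are on the linear (non-logarithmic) scale unless the caller
#' transformed them.
#'
#' Several features may map to one gene symbol (microarrays routinely carry
#' multiple probes per gene); identifiers are therefore probe/compound level
#' and the symbol map is carried alongside, not substituted in.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   row and column names set.
#' @param layer single string naming the omics layer.
#' @param symbols optional named character vector mapping feature identifiers
#'   to symbols (e.g. probe -> gene symbol).
#' @return an object of class `omics_matrix` (a numeric matrix with
#'   attributes `layer` and `symbols`).
#' @examples
#' x <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' m <- omics_matrix(x, "compound")
#' omics_layer(m)
#' @export
omics_matrix <- function(values, layer, symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) abort("empty matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) abort("row and column names are required")
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f)) abort("duplicate feature identifiers: %s", .listing(dup_f))
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s)) abort("duplicate sample identifiers: %s", .listing(dup_s))
  if (any(!is.finite(values))) abort("non-finite values in matrix")
  if (!is.character(layer) || length(layer) != 1L || !nzchar(layer)) {
    abort("'layer' must be a single non-empty string")
  }
  if (!is.null(symbols)) {
    if (is.null(names(symbols)) || !is.character(symbols)) {
      abort("'symbols' must be a named character vector (feature -> symbol)")
    }
  }
  structure(values, layer = layer, symbols = symbols,
            class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param m an `omics_matrix`.
#' @export
omics_layer <- function(m) attr(m, "layer")

#' @rdname omics_matrix
#' @export
feature_symbols <- function(m) attr(m, "symbols")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              omics_layer(x), nrow(x), ncol(x)))
  cat("samples:", .listing(colnames(x), 8), "\n")
  invisible(x)
}

#' Read a feature-by-sample matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers; the body must be fully numeric.  Tab-delimited is the
#' canonical dialect; pass `sep = ","` for CSV.
#'
#' @param path file path.
#' @param layer layer tag to attach (see [omics_matrix()]).
#' @param sep field separator (default tab).
#' @param log2 if `TRUE`, apply `log2()` to the values after reading
#'   (requires strictly positive input).  Off by default: values are used as
#'   provided.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer, sep = "\t", log2 = FALSE) {
  if (!file.exists(path)) abort("no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) abort("empty matrix in %s", path)
  fid <- df[[1L]]
  dup <- unique(fid[duplicated(fid)])
  if (length(dup)) abort("duplicate feature identifiers in %s: %s", path, .listing(dup))
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    abort("non-numeric cells in %s (e.g. feature '%s', sample '%s': '%s')",
          path, fid[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]],
          body[bad[1L, , drop = FALSE]])
  }
  if (anyNA(num)) abort("missing values in %s", path)
  dimnames(num) <- list(fid, colnames(df)[-1L])
  if (log2) {
    if (any(num <= 0)) abort("log2 transform requires strictly positive values")
    num <- log2(num)
  }
  omics_matrix(num, layer)
}

#' Write an omics matrix as delimited text
#'
#' Values are written with 17 significant digits so that
#' `write_omics_matrix()` followed by [read_omics_matrix()] round-trips
#' doubles bit-exactly.
#'
#' @param m an [omics_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "omics_matrix"))
  txt <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  out <- cbind(feature_id = rownames(m), txt)
  colnames(out) <- c("feature_id", colnames(m))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reorder all layers to one canonical sample order
#'
#' Cross-layer analyses require every layer to carry the same samples in the
#' same column order; this reorders each layer's columns to the sample order
#' of the design.  Layers whose sample set differs from the design's are
#' rejected with a listing of the discrepancy.  The operation is idempotent.
#'
#' @param layers a list of [omics_matrix()] objects (optionally named).
#' @param design a [sample_design()].
#' @return the list with every matrix's columns in design order.
#' @export
align_layers <- function(layers, design) {
  stopifnot(is.list(layers), inherits(design, "sample_design"))
  ord <- design$sample_id
  lapply(layers, function(m) {
    stopifnot(inherits(m, "omics_matrix"))
    missing_in_layer <- setdiff(ord, colnames(m))
    extra_in_layer <- setdiff(colnames(m), ord)
    if (length(missing_in_layer) || length(extra_in_layer)) {
      abort("layer '%s' sample set mismatch: missing [%s]; unexpected [%s]",
            omics_layer(m), .listing(missing_in_layer), .listing(extra_in_layer))
    }
    m[, ord, drop = FALSE]
  })
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "layer") <- attr(x, "layer")
    attr(out, "symbols") <- attr(x, "symbols")
    class(out) <- class(x)
  }
  out
}
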