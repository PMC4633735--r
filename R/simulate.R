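#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions the generator emulates: a four-class liver
#' cohort (10 ICC, 10 ICC_NT, 6 HCC, 6 HCC_NT = 32 samples) profiled on
#' three layers of very different dimensionality (150 compounds, 5000 mRNA
#' probes, 300 miRNA probes), with multiplicative (log-normal) noise and two
#' planted signal patterns per layer: features shifted in tumor samples
#' (ICC + HCC) and features shifted in ICC samples only.  The ICC-only shift
#' is scaled by `icc_contrast_multiplier` so that the ICC/ICC_NT separation
#' exceeds the HCC/HCC_NT separation, as observed in matched tumor cohorts
#' where cholangiocarcinoma diverges more from its surrounding tissue than
#' hepatocellular carcinoma does.
#'
#' All effect sizes and the noise standard deviation are on the log scale
#' (dimensionless); returned values are exponentiated and therefore strictly
#' positive, mimicking microarray intensities and metabolite abundances.
#'
#' @param n_samples_per_class named integer vector, class -> sample count.
#' @param n_features named integer vector, layer -> feature count.
#' @param n_planted_tumor named integer vector, layer -> number of features
#'   with a tumor-vs-non-tumor shift.
#' @param n_planted_icc named integer vector, layer -> number of features
#'   with an ICC-vs-rest shift (disjoint from the tumor set).
#' @param effect_size_tumor mean log-scale shift added to tumor samples of
#'   planted tumor-pattern features.
#' @param effect_size_icc mean log-scale shift for planted ICC-pattern
#'   features (applied to ICC samples only, scaled by
#'   `icc_contrast_multiplier`).
#' @param icc_contrast_multiplier factor >= 1 inflating the ICC shift.
#' @param noise_sd log-scale standard deviation of the per-observation noise
#'   (> 0).
#' @param baseline_log_mean,baseline_log_sd mean and sd of the per-feature
#'   baseline abundance on the log scale.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [simulate_multiomics()]
#' @export
synthetic_config <- function(n_samples_per_class = c(ICC = 10L, ICC_NT = 10L,
                                                     HCC = 6L, HCC_NT = 6L),
                             n_features = c(compound = 150L, mRNA = 5000L,
                                            miRNA = 300L),
                             n_planted_tumor = c(compound = 10L, mRNA = 40L,
                                                 miRNA = 12L),
                             n_planted_icc = c(compound = 10L, mRNA = 40L,
                                               miRNA = 12L),
                             effect_size_tumor = 3,
                             effect_size_icc = 3,
                             icc_contrast_multiplier = 1.5,
                             noise_sd = 1,
                             baseline_log_mean = 6,
                             baseline_log_sd = 1,
                             seed = 1L) {
  stopifnot(length(noise_sd) == 1L, length(seed) == 1L)
  if (!is.finite(noise_sd) || noise_sd <= 0) abort("noise_sd must be > 0")
  if (any(n_samples_per_class <= 0)) abort("all class sample counts must be positive")
  if (any(n_features <= 0)) abort("all layer feature counts must be positive")
  if (is.null(names(n_features))) abort("n_features must be named by layer")
  if (icc_contrast_multiplier < 1) abort("icc_contrast_multiplier must be >= 1")
  for (v in list(n_planted_tumor, n_planted_icc)) {
    if (!all(names(v) %in% names(n_features))) {
      abort("planted counts name unknown layers: %s",
            .listing(setdiff(names(v), names(n_features))))
    }
    if (any(v < 0)) abort("planted counts must be non-negative")
  }
  planted_count <- function(v, ly) {
    x <- unname(v[ly])
    if (length(x) != 1L || is.na(x)) 0L else as.integer(x)
  }
  for (ly in names(n_features)) {
    tot <- planted_count(n_planted_tumor, ly) + planted_count(n_planted_icc, ly)
    if (tot > n_features[[ly]]) {
      abort("layer '%s': planted features (%d) exceed layer size (%d)",
            ly, tot, n_features[[ly]])
    }
  }
  structure(list(n_samples_per_class = n_samples_per_class,
                 n_features = n_features,
                 n_planted_tumor = n_planted_tumor,
                 n_planted_icc = n_planted_icc,
                 effect_size_tumor = effect_size_tumor,
                 effect_size_icc = effect_size_icc,
                 icc_contrast_multiplier = icc_contrast_multiplier,
                 noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-layer dataset
#'
#' Draws, for every layer, a feature-by-sample matrix on the log scale:
#' per-feature baselines plus i.i.d. Gaussian noise, with the configured
#' class shifts added to the planted features (tumor-pattern features are
#' shifted in ICC and HCC samples; ICC-pattern features in ICC samples only,
#' by `effect_size_icc * icc_contrast_multiplier`).  Values are returned
#' exponentiated (linear scale).  The planted feature identifiers are
#' recorded per layer as ground truth for parameter-recovery checks.
#'
#' The generator restores the caller's RNG state on exit, so it neither
#' consumes nor perturbs the global random stream.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `layers` (named list of [omics_matrix()]), `design`
#'   ([sample_design()]), `truth` (per layer, character vectors `tumor` and
#'   `icc` of planted feature identifiers) and `config`.
#' @examples
#' ds <- simulate_multiomics(synthetic_config(
#'   n_features = c(compound = 30, mRNA = 50, miRNA = 20),
#'   n_planted_tumor = c(compound = 3, mRNA = 5, miRNA = 2),
#'   n_planted_icc = c(compound = 3, mRNA = 5, miRNA = 2)))
#' names(ds$layers)
#' @export
simulate_multiomics <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  cls <- config$n_samples_per_class
  class_vec <- rep(names(cls), times = cls)
  sample_ids <- unlist(lapply(names(cls), function(a)
    sprintf("%s_%02d", a, seq_len(cls[[a]]))), use.names = FALSE)
  design <- sample_design(sample_ids, class_vec, classes = names(cls))

  is_tumor <- class_vec %in% c("ICC", "HCC")
  is_icc <- class_vec == "ICC"

  layers <- list()
  truth <- list()
  for (ly in names(config$n_features)) {
    n <- config$n_features[[ly]]
    m <- length(sample_ids)
    fid <- sprintf("%s_%04d", ly, seq_len(n))
    pc <- function(v) {
      x <- unname(v[ly])
      if (length(x) != 1L || is.na(x)) 0L else as.integer(x)
    }
    n_t <- pc(config$n_planted_tumor)
    n_i <- pc(config$n_planted_icc)
    planted <- sample.int(n, n_t + n_i)
    idx_tumor <- planted[seq_len(n_t)]
    idx_icc <- planted[n_t + seq_len(n_i)]

    baseline <- stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    logx <- matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m) + baseline
    if (n_t > 0) {
      logx[idx_tumor, is_tumor] <- logx[idx_tumor, is_tumor] +
        config$effect_size_tumor
    }
    if (n_i > 0) {
      logx[idx_icc, is_icc] <- logx[idx_icc, is_icc] +
        config$effect_size_icc * config$icc_contrast_multiplier
    }
    dimnames(logx) <- list(fid, sample_ids)
    layers[[ly]] <- omics_matrix(exp(logx), ly)
    truth[[ly]] <- list(tumor = fid[sort(idx_tumor)], icc = fid[sort(idx_icc)])
  }
  structure(list(layers = layers, design = design, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples, %d layers (%s)\n",
              nrow(x$design), length(x$layers),
              paste(sprintf("%s: %d", names(x$layers),
                            vapply(x$layers, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' Per-class means of one feature
#'
#' Arithmetic mean of the linear-scale values of one feature within each
#' design class; a test/reporting helper.
#'
#' @param ds a [simulate_multiomics()] result (or any list with `layers` and
#'   `design`).
#' @param layer layer name.
#' @param feature feature identifier.
#' @return named numeric vector, one mean per class.
#' @export
class_means <- function(ds, layer, feature) {
  if (!layer %in% names(ds$layers)) abort("unknown layer '%s'", layer)
  m <- ds$layers[[layer]]
  if (!feature %in% rownames(m)) {
    abort("unknown feature '%s' in layer '%s'", feature, layer)
  }
  v <- m[feature, ds$design$sample_id]
  tapply(as.numeric(v), ds$design$class, mean)[levels(ds$design$class)]
}

#' Write a synthetic dataset to a run directory
#'
#' Writes each layer as a delimited matrix, the design as a two-column file,
#' the planted-truth lists as a two-column file (feature_id, pattern), and a
#' small JSON manifest recording the configuration and seed for
#' reproducibility.
#'
#' @param ds a [simulate_multiomics()] result.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_multiomics <- function(ds, dir, sep = "\t") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in names(ds$layers)) {
    write_omics_matrix(ds$layers[[ly]], file.path(dir, paste0(ly, "_matrix.tsv")), sep)
  }
  write_sample_design(ds$design, file.path(dir, "sample_design.tsv"), sep)
  truth <- do.call(rbind, lapply(names(ds$truth), function(ly) {
    t1 <- ds$truth[[ly]]
    rbind(
      if (length(t1$tumor)) data.frame(layer = ly, feature_id = t1$tumor,
                                       pattern = "tumor_vs_nontumor"),
      if (length(t1$icc)) data.frame(layer = ly, feature_id = t1$icc,
                                     pattern = "icc_vs_rest")
    )
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = sep,
                     quote = FALSE, row.names = FALSE)
  manifest <- list(generator = "pcaufe::simulate_multiomics",
                   package_version = as.character(utils::packageVersion("pcaufe")),
                   seed = ds$config$seed,
                   config = ds$config[setdiff(names(ds$config), "seed")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
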