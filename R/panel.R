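#' Genotype panel container
#'
#' A dosage matrix (samples x variants, entries in [0, 2]) together with its
#' variant metadata and a population label.
#'
#' @param dosages numeric matrix, n_samples x n_variants.
#' @param variants variant table as returned by [variant_table()]; row order
#'   must match the dosage columns.
#' @param sample_ids character vector of sample identifiers.
#' @param population population label.
#' @param drop_monomorphic drop zero-variance variants with a warning
#'   (default TRUE; set FALSE when key alignment across panels must be kept).
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL,
                           population = "unknown", drop_monomorphic = TRUE) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    tl_stop("dosage columns and variant rows differ in length", "transloci_validation")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (any(dosages < 0 | dosages > 2)) {
    tl_stop("dosages must lie in [0, 2]", "transloci_validation")
  }
  if (drop_monomorphic) {
    v <- matrixVar(dosages)
    if (any(v == 0)) {
      warning(sprintf("dropping %d monomorphic variant(s)", sum(v == 0)))
      dosages <- dosages[, v > 0, drop = FALSE]
      variants <- variants[v > 0, , drop = FALSE]
    }
  }
  colnames(dosages) <- variants$id
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids, population = population),
            class = "genotype_panel")
}

# internal: column variances without forming a copy per column
matrixVar <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Per-variant effect (alt) allele frequencies of a panel
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector, mean(dosage) / 2 per variant.
#' @export
panel_frequencies <- function(panel) {
  colMeans(panel$dosages) / 2
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (population: %s)\n",
              nrow(x$dosages), ncol(x$dosages), x$population))
  invisible(x)
}

#' Subset a panel to a set of variants (by id) and/or samples
#'
#' @param panel a `genotype_panel`.
#' @param variant_ids variant ids to keep (default all, original order kept).
#' @param sample_idx integer sample indices to keep (default all).
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, variant_ids = NULL, sample_idx = NULL) {
  vi <- if (is.null(variant_ids)) seq_len(ncol(panel$dosages)) else {
    m <- match(variant_ids, panel$variants$id)
    if (anyNA(m)) {
      tl_stop(sprintf("variant(s) absent from panel: %s",
                      paste(utils::head(variant_ids[is.na(m)], 5L), collapse = ", ")),
              "transloci_validation")
    }
    m
  }
  si <- if (is.null(sample_idx)) seq_len(nrow(panel$dosages)) else sample_idx
  genotype_panel(panel$dosages[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$sample_ids[si], panel$population,
                 drop_monomorphic = FALSE)
}
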