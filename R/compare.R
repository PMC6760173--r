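#' Bonferroni threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests (>= 1).
#' @return list with `threshold` (alpha / m, full precision) and `rounded`
#'   (two significant figures, the conventional reporting precision).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) tl_stop("m must be >= 1", "transloci_config")
  thr <- alpha / m
  list(threshold = thr, rounded = signif(thr, 2))
}

#' Label loci transferable / non-transferable / indeterminate
#'
#' A locus is `transferable` when its reproducibility call is a
#' credible-set hit and colocalization is significant (status ok and
#' p < `coloc_alpha`). It is `non_transferable` when colocalization gives no
#' support (p > `coloc_alpha` or a failed run), no variant in the region is
#' associated (reproducibility call `not_significant`), and the discovery
#' lead is not rare in the target (MAF >= `rare_threshold`). Everything else
#' - conflicting or missing evidence - is `indeterminate`.
#'
#' @param repro data.frame of [classify_locus()] rows (column id, category).
#' @param coloc data.frame with columns id, p_jlim, status.
#' @param target_maf named numeric vector (or data.frame id/maf) of lead
#'   minor-allele frequencies in the target.
#' @param coloc_alpha colocalization significance level (default 0.05).
#' @param rare_threshold MAF below which the lead counts as rare (default
#'   0.01, matching the score-construction rarity bound).
#' @return data.frame with id, label, repro_category, coloc_p, coloc_status,
#'   lead_maf, reason.
#' @export
label_loci <- function(repro, coloc, target_maf, coloc_alpha = 0.05,
                       rare_threshold = 0.01) {
  if (is.data.frame(target_maf)) {
    target_maf <- stats::setNames(target_maf$maf, target_maf$id)
  }
  ids <- repro$id
  cidx <- match(ids, coloc$id)
  maf <- unname(target_maf[ids])
  label <- character(length(ids))
  reason <- rep(NA_character_, length(ids))
  for (k in seq_along(ids)) {
    cat_k <- repro$category[k]
    if (is.na(cidx[k]) || is.na(maf[k])) {
      label[k] <- "indeterminate"
      reason[k] <- "missing_evidence"
      next
    }
    st <- coloc$status[cidx[k]]
    pj <- coloc$p_jlim[cidx[k]]
    coloc_pos <- identical(st, "ok") && !is.na(pj) && pj < coloc_alpha
    coloc_neg <- !identical(st, "ok") || (!is.na(pj) && pj > coloc_alpha)
    if (cat_k == "credible_set_hit" && coloc_pos) {
      label[k] <- "transferable"
    } else if (coloc_neg && cat_k == "not_significant" && maf[k] >= rare_threshold) {
      label[k] <- "non_transferable"
    } else {
      label[k] <- "indeterminate"
      reason[k] <- "conflicting_evidence"
    }
  }
  data.frame(id = ids, label = label, repro_category = repro$category,
             coloc_p = coloc$p_jlim[cidx], coloc_status = coloc$status[cidx],
             lead_maf = maf, reason = reason, stringsAsFactors = FALSE)
}

#' Count BMI-pleiotropic loci per transferability label
#'
#' @param records data.frame with a `bmi_p` column (e.g. the packaged BMI
#'   lookup from [load_bmi_lookup()]) plus a key column.
#' @param labels either a character vector aligned to `records` rows or a
#'   data.frame with columns matching `records` on `rsid`/`id` and a `label`
#'   column.
#' @param threshold Bonferroni-adjusted significance threshold.
#' @return data.frame with label, n (denominator) and n_bmi_associated
#'   (records with bmi_p < threshold).
#' @export
count_pleiotropy <- function(records, labels, threshold) {
  if (threshold <= 0) tl_stop("threshold must be > 0", "transloci_config")
  if (is.data.frame(labels)) {
    key <- if ("rsid" %in% names(labels)) "rsid" else "id"
    labels <- labels$label[match(records[[key]], labels[[key]])]
  }
  stopifnot(length(labels) == nrow(records))
  if (!nrow(records)) {
    return(data.frame(label = character(0), n = integer(0),
                      n_bmi_associated = integer(0)))
  }
  hit <- !is.na(records$bmi_p) & records$bmi_p < threshold
  agg <- tapply(hit, labels, function(h) c(n = length(h), hits = sum(h)))
  data.frame(label = names(agg),
             n = vapply(agg, `[[`, numeric(1), "n"),
             n_bmi_associated = vapply(agg, `[[`, numeric(1), "hits"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Load the packaged BMI pleiotropy lookup for lipid loci
#'
#' BMI association results (GIANT + UK Biobank meta-analysis, N >= 484,680)
#' for established lipid loci with clear evidence for or against
#' transferability to the Ugandan cohort. Columns: transferable (Yes/No),
#' trait, rsid, chrom, pos, gene (proximal gene annotation), bmi_beta,
#' bmi_se, bmi_p.
#'
#' @param path override the packaged file (mainly for tests).
#' @return data.frame.
#' @export
load_bmi_lookup <- function(path = system.file("extdata", "bmi_lipid_loci.tsv",
                                               package = "transloci")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer", bmi_beta = "numeric",
                                         bmi_se = "numeric", bmi_p = "numeric"))
  stopifnot(all(df$bmi_p > 0 & df$bmi_p <= 1))
  df
}

#' Assign the nearest protein-coding gene to loci
#'
#' @param loci data.frame with chrom, pos.
#' @param genes BED-like data.frame with chrom, start, end, name (caller
#'   supplied; no annotation database is bundled).
#' @return character vector of gene names (NA when the chromosome has no
#'   gene in the table).
#' @export
nearest_gene <- function(loci, genes) {
  vapply(seq_len(nrow(loci)), function(k) {
    g <- genes[genes$chrom == loci$chrom[k], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    d <- pmax(0, pmax(g$start - loci$pos[k], loci$pos[k] - g$end))
    g$name[which.min(d)]
  }, character(1))
}
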