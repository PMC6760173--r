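#' Cross-study variant filters for genetic risk scores
#'
#' A variant is kept only if it is present in every supplied study, common
#' (MAF >= `maf_min`) in every study, well imputed (info >= `info_min`) in
#' every study reporting imputation accuracy, and carries the same allele
#' pair as the discovery table (strand flips are tolerated for
#' non-palindromic pairs). The intersection rule keeps the score comparable
#' across studies.
#'
#' @param discovery data.frame with chrom, pos, effect_allele, other_allele,
#'   beta, discovery_p (and optionally trait, rsid).
#' @param studies named list of `genotype_panel` and/or `summary_stats`
#'   objects; summary stats may carry `eaf` and `info` columns.
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @param info_min imputation-accuracy floor (default 0.8).
#' @return list with `kept` (subset of discovery rows) and `exclusions`
#'   (data.frame variant, reason: absent / rare / badly_imputed /
#'   allele_mismatch).
#' @export
filter_variants <- function(discovery, studies, maf_min = 0.01, info_min = 0.8) {
  stopifnot(length(studies) >= 1)
  n <- nrow(discovery)
  reason <- rep(NA_character_, n)
  key_d <- paste(discovery$chrom, discovery$pos)
  for (study in studies) {
    if (inherits(study, "genotype_panel")) {
      key_s <- paste(study$variants$chrom, study$variants$pos)
      idx <- match(key_d, key_s)
      eaf <- panel_frequencies(study)[idx]
      info <- rep(NA_real_, n)
      a1 <- study$variants$alt[idx]; a2 <- study$variants$ref[idx]
    } else {
      key_s <- paste(study$chrom, study$pos)
      idx <- match(key_d, key_s)
      eaf <- study$eaf[idx]
      info <- if ("info" %in% names(study)) study$info[idx] else rep(NA_real_, n)
      a1 <- study$alt[idx]; a2 <- study$ref[idx]
    }
    absent <- is.na(idx)
    maf <- pmin(eaf, 1 - eaf)
    rare <- !absent & !is.na(maf) & maf < maf_min
    bad <- !absent & !is.na(info) & info < info_min
    orient <- rep("mismatch", n)
    ok <- !absent
    orient[ok] <- allele_orientation(discovery$effect_allele[ok],
                                     discovery$other_allele[ok],
                                     a1[ok], a2[ok])
    mism <- ok & !orient %in% c("same", "swap", "strand", "strand_swap")
    reason[is.na(reason) & absent] <- "absent"
    reason[is.na(reason) & rare] <- "rare"
    reason[is.na(reason) & bad] <- "badly_imputed"
    reason[is.na(reason) & mism] <- "allele_mismatch"
  }
  keep <- is.na(reason)
  if (!any(keep)) tl_stop("no variants survive the cross-study filters", "transloci_validation")
  vid <- if ("id" %in% names(discovery)) discovery$id else
    variant_id(discovery$chrom, discovery$pos,
               discovery$other_allele, discovery$effect_allele)
  list(kept = discovery[keep, , drop = FALSE],
       exclusions = data.frame(variant = vid[!keep], reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' LD pruning of score variants
#'
#' Removes the member with the larger discovery p-value from every pair of
#' variants correlated at r-squared above `r2_cap`. Implemented as a greedy
#' best-p-first pass (ties broken by position), which resolves chains
#' deterministically and guarantees no violating pair remains.
#'
#' @param variants data.frame with id, discovery_p, pos.
#' @param ld `ld_matrix` covering all the variants.
#' @param r2_cap pruning threshold (default 0.1, strict inequality retained:
#'   pairs at exactly the cap are kept).
#' @return the pruned subset of `variants`.
#' @export
ld_prune <- function(variants, ld, r2_cap = 0.1) {
  idx <- match(variants$id, ld$ids)
  if (anyNA(idx)) tl_stop("LD matrix does not cover all variants", "transloci_validation")
  r2 <- ld$r[idx, idx, drop = FALSE]^2
  ord <- order(variants$discovery_p, variants$pos)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(r2[i, kept] <= r2_cap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- variants[kept, , drop = FALSE]
  # post-hoc assertion: the pruned set must satisfy the cap
  rr <- r2[kept, kept, drop = FALSE]
  diag(rr) <- 0
  stopifnot(all(rr <= r2_cap))
  out
}

#' Assemble a weighted genetic risk score model
#'
#' @param variants filtered and pruned discovery variants (chrom, pos,
#'   effect_allele, other_allele, beta columns; beta is the discovery weight).
#' @param trait trait label.
#' @param exclusion_report optional data.frame accumulated during filtering.
#' @return object of class `grs_model`.
#' @export
grs_model <- function(variants, trait = NA_character_, exclusion_report = NULL) {
  stopifnot(all(c("chrom", "pos", "effect_allele", "beta") %in% names(variants)))
  structure(list(variants = variants, weights = variants$beta, trait = trait,
                 exclusion_report = exclusion_report),
            class = "grs_model")
}

#' Compute per-sample standardized risk scores
#'
#' Raw score = sum over model variants of weight x effect-allele dosage; the
#' output is scaled to mean 0, sd 1 so that downstream regression slopes are
#' correlation estimates. Model variants missing from the panel are an error
#' (silently skipping them would break cross-study comparability).
#'
#' @param panel a `genotype_panel` (harmonized to the model's effect alleles).
#' @param model a [grs_model()].
#' @return numeric vector of standardized scores.
#' @export
build_score <- function(panel, model) {
  key_m <- paste(model$variants$chrom, model$variants$pos)
  key_p <- paste(panel$variants$chrom, panel$variants$pos)
  idx <- match(key_m, key_p)
  if (anyNA(idx)) {
    tl_stop(sprintf("%d model variant(s) missing from the scoring panel",
                    sum(is.na(idx))), "transloci_validation")
  }
  D <- panel$dosages[, idx, drop = FALSE]
  # orient dosages to the model's effect allele
  flip <- model$variants$effect_allele == panel$variants$ref[idx]
  same <- model$variants$effect_allele == panel$variants$alt[idx]
  if (any(!flip & !same)) {
    tl_stop("panel alleles do not match the model; harmonize first",
            "transloci_validation")
  }
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  raw <- as.vector(D %*% model$weights)
  if (stats::var(raw) == 0) {
    tl_stop("raw score has zero variance and cannot be standardized",
            "transloci_degenerate")
  }
  (raw - mean(raw)) / stats::sd(raw)
}

#' Association between a risk score and a biomarker
#'
#' With both inputs standardized, the OLS slope of the phenotype on the score
#' equals their Pearson correlation. The p-value is the two-sided normal tail
#' of the score statistic z = r * sqrt(n); significance is flagged at the
#' Bonferroni level for a 3 x 3 score-by-biomarker grid (p < 0.05/9).
#'
#' @param score standardized score vector.
#' @param phenotype prepared (standardized) phenotype vector.
#' @param sig_threshold significance threshold (default 0.0056).
#' @return data.frame with r, se, p, n, significant.
#' @export
associate_score <- function(score, phenotype, sig_threshold = 0.0056) {
  if (length(score) != length(phenotype)) {
    tl_stop("score and phenotype lengths differ", "transloci_validation")
  }
  n <- length(score)
  s <- (score - mean(score)) / stats::sd(score)
  y <- (phenotype - mean(phenotype)) / stats::sd(phenotype)
  r <- sum(s * y) / (n - 1)
  se <- sqrt(pmax(1 - r^2, 1e-12) / (n - 2))
  z <- r * sqrt(n)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(r = r, se = se, p = p, n = n,
             significant = p < sig_threshold)
}

#' Cross-trait score-association matrix
#'
#' Associates each score with each biomarker, producing the 3 x 3 (or k x k)
#' grid used to inspect cross-trait sharing (e.g. the inverse HDL/TG
#' relationship).
#'
#' @param scores named list of standardized score vectors.
#' @param phenotypes named list of prepared phenotype vectors.
#' @param sig_threshold significance threshold (default 0.0056).
#' @return data.frame with score_trait, outcome_trait, r, se, p, n,
#'   significant.
#' @export
associate_score_matrix <- function(scores, phenotypes, sig_threshold = 0.0056) {
  rows <- list()
  for (st in names(scores)) {
    for (ot in names(phenotypes)) {
      a <- associate_score(scores[[st]], phenotypes[[ot]], sig_threshold)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(score_trait = st, outcome_trait = ot,
                   stringsAsFactors = FALSE), a)
    }
  }
  do.call(rbind, rows)
}
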