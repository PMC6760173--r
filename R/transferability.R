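#' Collapse multi-signal loci to their strongest variant
#'
#' Greedy pass in ascending discovery p-value: a hit within `window_bp` of an
#' already-kept hit on the same chromosome for the same trait is absorbed.
#'
#' @param hits data.frame with columns chrom, pos, trait, discovery_p (other
#'   columns are carried through).
#' @param window_bp absorption window (default 50000, closed interval).
#' @return data.frame of kept loci with an added logical column `major`
#'   (discovery_p < 1e-100).
#' @export
dedup_loci <- function(hits, window_bp = 50000) {
  stopifnot(all(c("chrom", "pos", "trait", "discovery_p") %in% names(hits)))
  ord <- order(hits$discovery_p, hits$chrom, hits$pos)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prior <- which(keep & hits$trait == hits$trait[i] &
                     hits$chrom == hits$chrom[i] &
                     abs(hits$pos - hits$pos[i]) <= window_bp)
    keep[i] <- !length(prior)
  }
  out <- hits[keep, , drop = FALSE]
  out$major <- out$discovery_p < 1e-100
  rownames(out) <- NULL
  out
}

#' Build the credible set of a locus
#'
#' The credible set is the lead variant plus every variant correlated with it
#' at r-squared strictly greater than `r2_threshold` in the reference panel.
#'
#' @param locus list/one-row data.frame with at least an `id` naming the lead
#'   variant (plus trait/discovery_p carried through).
#' @param ld an `ld_matrix` from the LD reference panel containing the lead.
#' @param r2_threshold LD threshold (default 0.6, strict inequality).
#' @return object of class `credible_set`: list with `locus`, `members`
#'   (variant ids, lead first) and `reference` (the panel label if known).
#' @export
build_credible_set <- function(locus, ld, r2_threshold = 0.6) {
  lead_id <- as.character(locus$id)
  if (!lead_id %in% ld$ids) {
    tl_stop(sprintf("lead variant %s absent from the LD matrix", lead_id),
            "transloci_validation")
  }
  r2 <- ld$r[, lead_id]^2
  members <- ld$ids[r2 > r2_threshold]
  members <- union(lead_id, members)
  structure(list(locus = locus, members = members,
                 reference = attr(ld, "reference") %||% NA_character_),
            class = "credible_set")
}

#' Empirical assessment of the reproducibility p-value threshold
#'
#' Draws `n_windows` random windows of `width_bp` uniformly over the
#' positions covered by the target summary statistics and records the
#' minimum p-value in each. A threshold of 1e-3 is considered usable for the
#' study when fewer than 5% of random windows attain it.
#'
#' @param target `summary_stats` for the target study.
#' @param n_windows number of random windows (default 1000).
#' @param width_bp window width (default 50000).
#' @param seed RNG seed.
#' @param p_threshold the candidate threshold (default 1e-3).
#' @return list with `proportion` (windows with min p below threshold),
#'   `pass` (proportion < 0.05), `min_p` (per-window minima) and the window
#'   draw parameters.
#' @export
empirical_threshold <- function(target, n_windows = 1000, width_bp = 50000,
                                seed = 1, p_threshold = 1e-3) {
  spans <- tapply(target$pos, target$chrom, function(p) max(p) - min(p))
  if (sum(spans) < n_windows * width_bp) {
    tl_stop("target coverage too small for the requested number of windows; use fewer or narrower windows",
            "transloci_validation")
  }
  set.seed(seed)
  chroms <- sample(names(spans), n_windows, replace = TRUE,
                   prob = spans / sum(spans))
  min_p <- rep(NA_real_, n_windows)
  for (k in seq_len(n_windows)) {
    rows <- which(target$chrom == chroms[k])
    lo <- min(target$pos[rows])
    hi <- max(target$pos[rows])
    start <- lo + stats::runif(1) * max(hi - lo - width_bp, 0)
    inw <- rows[target$pos[rows] >= start & target$pos[rows] <= start + width_bp]
    if (length(inw)) min_p[k] <- min(target$p[inw])
  }
  covered <- !is.na(min_p)
  proportion <- mean(min_p[covered] < p_threshold)
  list(proportion = proportion, pass = proportion < 0.05,
       min_p = min_p, n_windows = n_windows, width_bp = width_bp,
       p_threshold = p_threshold)
}

#' Classify reproducibility of one locus in a target study
#'
#' A locus is a `credible_set_hit` when any credible-set member is associated
#' in the target at p below `p_threshold`; otherwise a `region_hit` when any
#' variant within `region_halfwidth` of the lead reaches the threshold;
#' otherwise `not_significant`. Regions with no target variants at all are
#' flagged `indeterminate` (distinct from a clean negative).
#'
#' @param cs a [build_credible_set()] result; its locus must carry chrom/pos.
#' @param target `summary_stats` of the target study, harmonized keys.
#' @param p_threshold association threshold (default 1e-3, strict).
#' @param region_halfwidth region half width (default 25000 bp).
#' @return data.frame row: locus id, trait, major, category, best_p_credible,
#'   best_p_region, n_members_tested.
#' @export
classify_locus <- function(cs, target, p_threshold = 1e-3,
                           region_halfwidth = 25000) {
  locus <- cs$locus
  member_rows <- match(cs$members, target$id)
  found <- !is.na(member_rows)
  if (any(!found)) {
    message(sprintf("locus %s: %d credible-set member(s) missing from target",
                    as.character(locus$id), sum(!found)))
  }
  best_credible <- if (any(found)) min(target$p[member_rows[found]]) else NA_real_
  in_region <- target$chrom == as.character(locus$chrom) &
    abs(target$pos - as.integer(locus$pos)) <= region_halfwidth
  best_region <- if (any(in_region)) min(target$p[in_region]) else NA_real_
  category <- if (!any(in_region) && !any(found)) {
    "indeterminate"
  } else if (any(found) && best_credible < p_threshold) {
    "credible_set_hit"
  } else if (any(in_region) && best_region < p_threshold) {
    "region_hit"
  } else {
    "not_significant"
  }
  data.frame(id = as.character(locus$id),
             trait = if (!is.null(locus$trait)) as.character(locus$trait) else NA_character_,
             major = if (!is.null(locus$major)) locus$major else NA,
             category = category,
             best_p_credible = best_credible,
             best_p_region = best_region,
             n_members_tested = sum(found),
             stringsAsFactors = FALSE)
}

#' Reproducibility rate table
#'
#' Percentage of loci per category, stratified by trait and by major/minor
#' discovery strength. Indeterminate loci are excluded from the denominator
#' and reported in their own column.
#'
#' @param calls data.frame of [classify_locus()] rows.
#' @return data.frame with columns trait, major, n, pct_not_significant,
#'   pct_region_hit, pct_credible_set_hit, n_indeterminate; the three
#'   percentages sum to 100 per row (up to rounding).
#' @export
rate_table <- function(calls) {
  stopifnot(all(c("trait", "major", "category") %in% names(calls)))
  strata <- unique(calls[, c("trait", "major")])
  strata <- strata[order(strata$trait, !strata$major), , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(k) {
    sel <- calls$trait == strata$trait[k] & calls$major == strata$major[k]
    sub <- calls[sel, , drop = FALSE]
    ind <- sub$category == "indeterminate"
    n <- sum(!ind)
    pct <- function(cat) if (n) 100 * sum(sub$category == cat) / n else NA_real_
    data.frame(trait = strata$trait[k], major = strata$major[k], n = n,
               pct_not_significant = pct("not_significant"),
               pct_region_hit = pct("region_hit"),
               pct_credible_set_hit = pct("credible_set_hit"),
               n_indeterminate = sum(ind),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
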