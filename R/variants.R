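#' Canonical variant identifiers
#'
#' Variants are keyed by chromosome, 1-based position and allele pair. The
#' canonical string form is `chrom:pos:ref:alt`, which is used as the column
#' name in dosage matrices and as the join key across datasets.
#'
#' @param chrom chromosome label (character or coercible).
#' @param pos 1-based base position.
#' @param ref,alt reference / alternate alleles (uppercase A/C/G/T for SNVs).
#' @return character vector of variant ids.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(as.character(chrom), as.integer(pos), toupper(ref), toupper(alt), sep = ":")
}

#' Build and validate a variant table
#'
#' @param chrom,pos,ref,alt per-variant fields; see [variant_id()].
#' @param rsid optional rs identifiers (NA where unknown).
#' @return data.frame with columns chrom, pos, ref, alt, rsid, id.
#' @export
variant_table <- function(chrom, pos, ref, alt, rsid = NA_character_) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(pos < 1L)) tl_stop("variant positions must be >= 1", "transloci_validation")
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  ok <- !snv | (ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"))
  if (!all(ok)) {
    tl_stop(sprintf("invalid SNV alleles at rows: %s",
                    paste(utils::head(which(!ok), 5L), collapse = ", ")),
            "transloci_validation")
  }
  if (any(ref == alt)) tl_stop("ref and alt alleles must differ", "transloci_validation")
  id <- variant_id(chrom, pos, ref, alt)
  # uniqueness up to allele order within a dataset
  sorted_key <- paste(chrom, pos,
                      ifelse(ref < alt, paste(ref, alt), paste(alt, ref)))
  if (anyDuplicated(sorted_key)) {
    dup <- unique(id[duplicated(sorted_key)])
    tl_stop(sprintf("duplicate variant keys: %s",
                    paste(utils::head(dup, 5L), collapse = ", ")),
            "transloci_duplicate")
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             rsid = rep_len(as.character(rsid), length(chrom)),
             id = id, stringsAsFactors = FALSE)
}

# internal: DNA complement for strand-flip resolution
allele_complement <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

# internal: TRUE for palindromic (strand-ambiguous) SNPs: A/T or C/G
is_palindromic <- function(a1, a2) {
  toupper(a1) == allele_complement(a2)
}

# internal: classify the orientation of a target allele pair against a
# reference pair. Returns one of "same", "swap", "strand", "strand_swap",
# "palindromic", "mismatch". The eight possible orientations of two
# biallelic non-palindromic SNPs collapse onto these cases.
allele_orientation <- function(t_eff, t_oth, r_eff, r_oth) {
  t_eff <- toupper(t_eff); t_oth <- toupper(t_oth)
  r_eff <- toupper(r_eff); r_oth <- toupper(r_oth)
  out <- rep("mismatch", length(t_eff))
  pal <- is_palindromic(t_eff, t_oth) | is_palindromic(r_eff, r_oth)
  same <- t_eff == r_eff & t_oth == r_oth
  swap <- t_eff == r_oth & t_oth == r_eff
  strand <- allele_complement(t_eff) == r_eff & allele_complement(t_oth) == r_oth
  strand_swap <- allele_complement(t_eff) == r_oth & allele_complement(t_oth) == r_eff
  out[strand_swap] <- "strand_swap"
  out[strand] <- "strand"
  out[swap] <- "swap"
  out[same] <- "same"
  out[pal] <- "palindromic"
  out
}

#' Harmonize a dataset's alleles to a reference variant table
#'
#' Aligns effect alleles of summary statistics, or the counted (alt) allele
#' of a genotype panel, to the effect alleles of a reference table. Variants
#' are matched by (chrom, pos), falling back to rsid when the position is
#' absent from the reference. Same-orientation variants pass unchanged;
#' ref/alt swaps flip the sign of beta and z, complement the effect-allele
#' frequency, and reflect dosages (2 - dosage); unambiguous strand flips
#' (A<->T, C<->G complements) are relabelled to the reference strand.
#' Palindromic (A/T, C/G) variants and unresolvable allele pairs are
#' excluded, never rescued by frequency.
#'
#' @param target a `summary_stats` data.frame or a `genotype_panel`.
#' @param reference data.frame with columns chrom, pos, effect_allele,
#'   other_allele (optional rsid).
#' @return list with `data` (harmonized target, reference orientation) and
#'   `exclusions` (data.frame variant, reason).
#' @export
harmonize_alleles <- function(target, reference) {
  stopifnot(all(c("chrom", "pos", "effect_allele", "other_allele") %in% names(reference)))
  if (inherits(target, "genotype_panel")) {
    harmonize_panel(target, reference)
  } else {
    harmonize_stats(target, reference)
  }
}

# internal: match target rows to reference rows by (chrom,pos), rsid fallback
match_reference <- function(chrom, pos, rsid, reference) {
  key_t <- paste(chrom, pos)
  key_r <- paste(reference$chrom, reference$pos)
  idx <- match(key_t, key_r)
  if (!is.null(rsid) && "rsid" %in% names(reference)) {
    miss <- is.na(idx) & !is.na(rsid)
    idx[miss] <- match(rsid[miss], reference$rsid)
  }
  idx
}

harmonize_stats <- function(stats, reference) {
  oth <- ifelse(stats$effect_allele == stats$alt, stats$ref, stats$alt)
  idx <- match_reference(stats$chrom, stats$pos, stats$rsid, reference)
  orient <- rep("not_in_reference", nrow(stats))
  m <- !is.na(idx)
  orient[m] <- allele_orientation(stats$effect_allele[m], oth[m],
                                  reference$effect_allele[idx[m]],
                                  reference$other_allele[idx[m]])
  keep <- orient %in% c("same", "swap", "strand", "strand_swap")
  flip <- orient %in% c("swap", "strand_swap")
  out <- stats[keep, , drop = FALSE]
  fl <- flip[keep]
  out$beta[fl] <- -out$beta[fl]
  if ("z" %in% names(out)) out$z[fl] <- -out$z[fl]
  if ("eaf" %in% names(out)) out$eaf[fl] <- 1 - out$eaf[fl]
  # relabel onto the reference strand/orientation
  ridx <- idx[keep]
  out$effect_allele <- reference$effect_allele[ridx]
  oth_ref <- reference$other_allele[ridx]
  # alt carries the effect allele after harmonization
  out$alt <- out$effect_allele
  out$ref <- oth_ref
  out$id <- variant_id(out$chrom, out$pos, out$ref, out$alt)
  excl <- data.frame(variant = stats$id[!keep],
                     reason = orient[!keep], stringsAsFactors = FALSE)
  list(data = out, exclusions = excl)
}

harmonize_panel <- function(panel, reference) {
  v <- panel$variants
  idx <- match_reference(v$chrom, v$pos, v$rsid, reference)
  orient <- rep("not_in_reference", nrow(v))
  m <- !is.na(idx)
  # a panel's counted allele is alt
  orient[m] <- allele_orientation(v$alt[m], v$ref[m],
                                  reference$effect_allele[idx[m]],
                                  reference$other_allele[idx[m]])
  keep <- orient %in% c("same", "swap", "strand", "strand_swap")
  flip <- orient %in% c("swap", "strand_swap")
  dos <- panel$dosages[, keep, drop = FALSE]
  fl <- flip[keep]
  dos[, fl] <- 2 - dos[, fl, drop = FALSE]
  ridx <- idx[keep]
  v2 <- v[keep, , drop = FALSE]
  v2$alt <- reference$effect_allele[ridx]
  v2$ref <- reference$other_allele[ridx]
  v2$id <- variant_id(v2$chrom, v2$pos, v2$ref, v2$alt)
  colnames(dos) <- v2$id
  excl <- data.frame(variant = v$id[!keep],
                     reason = orient[!keep], stringsAsFactors = FALSE)
  list(data = genotype_panel(dos, v2, panel$sample_ids, panel$population,
                             drop_monomorphic = FALSE),
       exclusions = excl)
}

#' Write an exclusion report
#'
#' @param exclusions data.frame with columns variant, reason.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_exclusion_report <- function(exclusions, path) {
  utils::write.table(exclusions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
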