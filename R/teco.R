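#' Single-causal-variant likelihood over a window
#'
#' Under the single-causal model the vector of score statistics is
#' multivariate normal, z ~ N(lambda * r_.i, R), for causal variant i with
#' unknown signal strength lambda. Profiling the MVN density over lambda
#' collapses to L(i) proportional to exp(z_i^2 / 2): because R^{-1} r_.i is
#' the i-th unit vector, the generalized least squares projection of z onto
#' r_.i is simply z_i. The returned vector is normalized to sum to one
#' (computed with a max shift so large z do not overflow).
#'
#' @param z score-statistic vector over the window variants.
#' @param ld optional `ld_matrix` (accepted for interface symmetry; the
#'   profile likelihood does not depend on it, see above).
#' @return normalized likelihood vector L with sum(L) = 1.
#' @export
single_causal_likelihood <- function(z, ld = NULL) {
  if (!length(z)) tl_stop("empty window", "transloci_validation")
  if (any(!is.finite(z))) tl_stop("z must be finite", "transloci_validation")
  h <- z^2 / 2
  w <- exp(h - max(h))
  w / sum(w)
}

#' Joint-likelihood-mapping statistic for two association signals
#'
#' Computes
#' \deqn{\Lambda = \sum_{i \in N^1_\theta(m^*)} L_1(i) \log
#'   \frac{L_1(i) L_2(i)}{\max_{j \notin N^2_\theta(i)} L_1(i) L_2(j)}}
#' where \eqn{N_\theta(i)} is the set of variants in LD with i at r-squared
#' at least theta (in cohort 1 around the lead m*, in cohort 2 around each
#' summed i). Positive values indicate that the second cohort's likelihood
#' mass falls inside the lead variant's LD neighborhood (shared signal);
#' negative values indicate mass outside it (distinct signals). Note that
#' L_1(i) cancels inside the log ratio; the sum is computed as printed.
#'
#' @param L1,L2 normalized single-causal likelihood vectors (cohort 1 and 2).
#' @param ld1,ld2 `ld_matrix` objects (or plain correlation matrices) for the
#'   two cohorts, over the same variants in the same order.
#' @param lead index of the lead variant m* (cohort 1).
#' @param theta LD threshold on r-squared (default 0.8).
#' @return list with `lambda` (NA unless status is "ok"), `status` ("ok",
#'   "failed_single_snp" or "failed_no_complement") and `n_terms` (number of
#'   neighborhood variants contributing).
#' @export
jlim_lambda <- function(L1, L2, ld1, ld2, lead, theta = 0.8) {
  r1 <- if (inherits(ld1, "ld_matrix")) ld1$r else ld1
  r2 <- if (inherits(ld2, "ld_matrix")) ld2$r else ld2
  m <- length(L1)
  stopifnot(length(L2) == m, nrow(r1) == m, nrow(r2) == m,
            lead >= 1, lead <= m)
  if (m == 1L) {
    return(list(lambda = NA_real_, status = "failed_single_snp", n_terms = 0L))
  }
  neighborhood <- which(r1[, lead]^2 >= theta)
  logL1 <- log(L1)
  logL2 <- log(L2)
  lambda <- 0
  n_terms <- 0L
  for (i in neighborhood) {
    complement <- which(r2[i, ]^2 < theta)
    if (!length(complement)) next
    num <- logL1[i] + logL2[i]
    den <- logL1[i] + max(logL2[complement])
    lambda <- lambda + L1[i] * (num - den)
    n_terms <- n_terms + 1L
  }
  if (n_terms == 0L) {
    return(list(lambda = NA_real_, status = "failed_no_complement", n_terms = 0L))
  }
  list(lambda = lambda, status = "ok", n_terms = n_terms)
}

# internal: batched lambda over B columns of squared score statistics.
# Exploits the closed form: with L(i) prop exp(z_i^2/2), the log ratio in the
# statistic reduces to (z_i^2 - max_complement z_j^2) / 2, so the window
# normalization cancels and no exponentials are needed. Equivalent to
# jlim_lambda() applied column-by-column (see tests).
jlim_lambda_batch <- function(L1, z2sq, r1sq_lead, r2sq, theta = 0.8) {
  m <- length(L1)
  if (m == 1L) {
    return(list(lambda = rep(NA_real_, ncol(z2sq)), status = "failed_single_snp"))
  }
  neighborhood <- which(r1sq_lead >= theta)
  lambda <- numeric(ncol(z2sq))
  n_terms <- 0L
  for (i in neighborhood) {
    complement <- r2sq[i, ] < theta
    if (!any(complement)) next
    cmax <- apply(z2sq[complement, , drop = FALSE], 2L, max)
    lambda <- lambda + L1[i] * (z2sq[i, ] - cmax) / 2
    n_terms <- n_terms + 1L
  }
  if (n_terms == 0L) {
    return(list(lambda = rep(NA_real_, ncol(z2sq)), status = "failed_no_complement"))
  }
  list(lambda = lambda, status = "ok", n_terms = n_terms)
}

#' Bundle the inputs of one colocalization test
#'
#' @param z1 reference-cohort score statistics over the window variants.
#' @param ld1 `ld_matrix` from an ancestry-matched reference panel.
#' @param target_panel `genotype_panel` with raw target genotypes over the
#'   same variants (same order).
#' @param target_phenotype prepared (standardized) target phenotype.
#' @param lead index of the reference lead variant m* within the window.
#' @param theta LD threshold (default 0.8).
#' @return object of class `coloc_input`.
#' @export
coloc_input <- function(z1, ld1, target_panel, target_phenotype, lead,
                        theta = 0.8) {
  r1 <- if (inherits(ld1, "ld_matrix")) ld1$r else ld1
  m <- length(z1)
  if (nrow(r1) != m || ncol(target_panel$dosages) != m) {
    tl_stop("z1, ld1 and target panel must cover the same variants", "transloci_validation")
  }
  if (length(target_phenotype) != nrow(target_panel$dosages)) {
    tl_stop("target phenotype length does not match panel", "transloci_validation")
  }
  if (theta <= 0 || theta >= 1) tl_stop("theta must be in (0, 1)", "transloci_config")
  if (lead < 1 || lead > m) tl_stop("lead outside window", "transloci_validation")
  structure(list(z1 = z1, r1 = r1, target_panel = target_panel,
                 target_phenotype = as.numeric(target_phenotype),
                 lead = lead, theta = theta),
            class = "coloc_input")
}

#' Permutation p-value for trans-ethnic colocalization
#'
#' The observed statistic uses score-test z's of the target phenotype on the
#' window dosages. For each permutation the target phenotype labels are
#' shuffled and the target z's and the statistic recomputed, with the
#' reference likelihood and both LD matrices held fixed. The p-value uses
#' the add-one estimator p = (1 + #\{lambda_b >= lambda_obs\}) / (B + 1);
#' ties count towards the numerator.
#'
#' @param input a [coloc_input()].
#' @param B number of permutations (>= 100).
#' @param seed RNG seed.
#' @return object of class `coloc_result`: list with lambda_stat, p_jlim,
#'   n_permutations, status, z2 (observed target statistics) and lead.
#' @export
permutation_p <- function(input, B = 1000, seed = 1) {
  stopifnot(inherits(input, "coloc_input"))
  if (B < 100) tl_stop("B must be >= 100", "transloci_config")
  n <- nrow(input$target_panel$dosages)
  if (n < 50) tl_stop("target panel must have >= 50 samples", "transloci_validation")
  v <- matrixVar(input$target_panel$dosages)
  if (any(v == 0)) {
    tl_stop("monomorphic variant in target window; harmonize/filter first",
            "transloci_degenerate")
  }
  xs <- standardize_columns(input$target_panel$dosages)
  r2 <- crossprod(xs) / (n - 1)
  coloc_perm_core(xs, input$target_phenotype, input$z1, input$r1^2, r2^2,
                  input$lead, input$theta, B, seed)
}

# internal engine shared by permutation_p() and the simulation study.
# xs: standardized target dosages; r1sq/r2sq: squared LD matrices.
coloc_perm_core <- function(xs, y, z1, r1sq, r2sq, lead, theta, B, seed) {
  n <- nrow(xs)
  ys <- (y - mean(y)) / stats::sd(y)
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  Y <- cbind(ys, matrix(ys[perm], nrow = n))
  Z <- crossprod(xs, Y) * (sqrt(n) / (n - 1))   # z = r * sqrt(n), all columns
  L1 <- single_causal_likelihood(z1)
  res <- jlim_lambda_batch(L1, Z^2, r1sq[, lead], r2sq, theta)
  if (res$status != "ok") {
    return(structure(list(lambda_stat = NA_real_, p_jlim = NA_real_,
                          n_permutations = B, status = res$status,
                          z2 = Z[, 1], lead = lead),
                     class = "coloc_result"))
  }
  lambda_obs <- res$lambda[1]
  lambda_perm <- res$lambda[-1]
  p <- (1 + sum(lambda_perm >= lambda_obs)) / (B + 1)
  structure(list(lambda_stat = lambda_obs, p_jlim = p, n_permutations = B,
                 status = "ok", z2 = Z[, 1], lead = lead),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: lambda = %s, p_jlim = %s (B = %d, status = %s)\n",
              format(x$lambda_stat, digits = 4), format(x$p_jlim, digits = 4),
              x$n_permutations, x$status))
  invisible(x)
}

#' MHC region excluded from colocalization
#'
#' The major histocompatibility complex (chr6:28,477,797-33,448,354) is
#' excluded because its LD structure violates the single-causal assumption.
#'
#' @return list with chrom, start, end.
#' @export
mhc_region <- function() {
  list(chrom = "6", start = 28477797L, end = 33448354L)
}

#' Run trans-ethnic colocalization for one locus
#'
#' Builds the 50 Kb window (lead +/- `halfwidth`) over the variants shared by
#' the reference summary statistics, the reference LD panel and the target
#' panel, excludes MHC-overlapping loci, and runs the permutation test.
#'
#' @param locus list or one-row data.frame with chrom, pos (lead variant
#'   position) and optionally id/rsid.
#' @param ref_stats harmonized `summary_stats` for the reference cohort.
#' @param ref_ld_panel ancestry-matched reference `genotype_panel` for LD.
#' @param target_panel target-cohort `genotype_panel` (raw genotypes).
#' @param target_phenotype prepared target phenotype.
#' @param theta LD threshold (default 0.8).
#' @param B permutation count.
#' @param seed RNG seed.
#' @param halfwidth window half width in bp (default 25000, closed interval).
#' @param min_variants minimum shared variants required (default 5).
#' @return a `coloc_result`; status "excluded_mhc" or
#'   "failed_insufficient_variants" short-circuits the test.
#' @export
run_coloc <- function(locus, ref_stats, ref_ld_panel, target_panel,
                      target_phenotype, theta = 0.8, B = 1000, seed = 1,
                      halfwidth = 25000, min_variants = 5) {
  chrom <- as.character(locus$chrom)
  pos <- as.integer(locus$pos)
  mhc <- mhc_region()
  if (chrom == mhc$chrom &&
      pos + halfwidth >= mhc$start && pos - halfwidth <= mhc$end) {
    return(structure(list(lambda_stat = NA_real_, p_jlim = NA_real_,
                          n_permutations = 0L, status = "excluded_mhc",
                          z2 = NULL, lead = NA_integer_),
                     class = "coloc_result"))
  }
  in_window <- ref_stats$chrom == chrom & abs(ref_stats$pos - pos) <= halfwidth
  ids <- Reduce(intersect, list(ref_stats$id[in_window],
                                ref_ld_panel$variants$id,
                                target_panel$variants$id))
  if (length(ids) < min_variants) {
    message(sprintf("locus %s:%d: only %d shared variant(s) in window",
                    chrom, pos, length(ids)))
    return(structure(list(lambda_stat = NA_real_, p_jlim = NA_real_,
                          n_permutations = 0L,
                          status = "failed_insufficient_variants",
                          z2 = NULL, lead = NA_integer_),
                     class = "coloc_result"))
  }
  widx <- match(ids, ref_stats$id)
  z1 <- ref_stats$z[widx]
  ld1 <- ld_matrix(subset_panel(ref_ld_panel, ids))
  tp <- subset_panel(target_panel, ids)
  lead_pos <- ref_stats$pos[widx]
  lead <- which(lead_pos == pos)
  if (!length(lead)) lead <- which.max(z1^2) else lead <- lead[1]
  input <- coloc_input(z1, ld1, tp, target_phenotype, lead, theta)
  permutation_p(input, B = B, seed = seed)
}
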