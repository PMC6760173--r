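#' Population model for the synthetic genotype generator
#'
#' The generator builds a pool of ancestral haplotypes as recombinant mosaics
#' of a small founder set, which induces linkage disequilibrium that decays
#' with distance at a rate governed by the per-base crossover probability.
#' Populations are then derived from the pool under Balding-Nichols drift.
#'
#' @param n_variants number of variants in the locus window.
#' @param n_founders number of founder haplotypes (the source of LD).
#' @param n_ancestral_haplotypes size of the mosaic haplotype pool.
#' @param recomb_rate per-base crossover probability used in the mosaic
#'   resampling.
#' @param spacing_bp distance between adjacent variants (default 500 bp, so
#'   100 variants span a 50 Kb window).
#' @param maf_floor minimum ancestral minor-allele frequency, in [0, 0.5).
#' @param divergence_f default Balding-Nichols drift parameter F in [0, 1).
#' @param chrom chromosome label given to generated variants.
#' @param start_bp position of the first variant.
#' @return object of class `population_model`.
#' @export
population_model <- function(n_variants = 100, n_founders = 16,
                             n_ancestral_haplotypes = 200,
                             recomb_rate = 1e-5, spacing_bp = 500,
                             maf_floor = 0.05, divergence_f = 0.1,
                             chrom = "1", start_bp = 1000000) {
  if (n_variants < 2) tl_stop("n_variants must be >= 2", "transloci_config")
  if (n_founders < 1) tl_stop("at least one founder haplotype is required", "transloci_config")
  if (maf_floor < 0 || maf_floor >= 0.5) tl_stop("maf_floor must be in [0, 0.5)", "transloci_config")
  if (divergence_f < 0 || divergence_f >= 1) tl_stop("divergence_f must be in [0, 1)", "transloci_config")
  structure(list(n_variants = n_variants, n_founders = n_founders,
                 n_ancestral_haplotypes = n_ancestral_haplotypes,
                 recomb_rate = recomb_rate, spacing_bp = spacing_bp,
                 maf_floor = maf_floor, divergence_f = divergence_f,
                 chrom = chrom, start_bp = start_bp),
            class = "population_model")
}

#' Simulate an ancestral haplotype pool
#'
#' Ancestral allele frequencies are uniform on [maf_floor, 1 - maf_floor]
#' marginally and locally correlated along the chromosome (as in descent);
#' founder haplotypes carry distance-decaying correlation and are thresholded
#' at those frequencies; pool haplotypes are founder mosaics with crossover
#' probability `1 - (1 - recomb_rate)^spacing_bp` between adjacent variants.
#' With few founders, nearby variants share founder origin and are therefore
#' correlated; the correlation decays as crossovers accumulate.
#'
#' @param model a [population_model()].
#' @param seed RNG seed.
#' @return object of class `haplotype_pool`: binary matrix `haplotypes`
#'   (pool x variants), realized ancestral frequencies `freqs` (the pool is
#'   the ancestral population; `target_freqs` keeps the uniform draws),
#'   `positions`, a `variants` table shared by every panel derived from the
#'   pool, and the model.
#' @export
simulate_ancestral_haplotypes <- function(model, seed = 1) {
  set.seed(seed)
  m <- model$n_variants
  k <- model$n_founders
  n_hap <- model$n_ancestral_haplotypes
  positions <- model$start_bp + (seq_len(m) - 1L) * model$spacing_bp
  p_switch <- 1 - (1 - model$recomb_rate)^model$spacing_bp
  rho <- 1 - p_switch
  # Ancestral frequencies: uniform on [maf_floor, 1 - maf_floor] marginally,
  # but locally correlated along the chromosome (probability transform of an
  # AR(1) process). Variants that descend together have similar frequencies;
  # without this the frequency mismatch between neighbours caps the
  # attainable r2 far below what real haplotype blocks show.
  g <- stats::rnorm(m)
  if (m > 1) for (j in 2:m) g[j] <- rho * g[j - 1] + sqrt(1 - rho^2) * g[j]
  freqs <- model$maf_floor + (1 - 2 * model$maf_floor) * stats::pnorm(g)
  # Founders carry their own distance-decaying correlation via a latent
  # AR(1) Gaussian copula (coefficient tied to the crossover probability),
  # thresholded at the ancestral frequencies. Without this, alleles at
  # linked sites would be independent across founders and the pool would
  # have no usable LD however few founders there are.
  Zl <- matrix(stats::rnorm(k * m), nrow = k)
  if (m > 1) {
    for (j in 2:m) Zl[, j] <- rho * Zl[, j - 1] + sqrt(1 - rho^2) * Zl[, j]
  }
  founders <- matrix(0L, nrow = k, ncol = m)
  founders[Zl < rep(stats::qnorm(freqs), each = k)] <- 1L
  f <- matrix(0L, nrow = n_hap, ncol = m)
  f[, 1] <- sample.int(k, n_hap, replace = TRUE)
  if (m > 1) {
    for (j in 2:m) {
      sw <- stats::runif(n_hap) < p_switch
      f[, j] <- ifelse(sw, sample.int(k, n_hap, replace = TRUE), f[, j - 1])
    }
  }
  H <- matrix(0L, nrow = n_hap, ncol = m)
  for (j in seq_len(m)) H[, j] <- founders[f[, j], j]
  # the pool is the ancestral population: its realized frequencies are the
  # ancestral frequencies that drift is centred on downstream
  pool_freqs <- colMeans(H)
  # alternate non-palindromic allele pairs so strand logic stays exercised
  refs <- rep(c("A", "C"), length.out = m)
  alts <- rep(c("G", "T"), length.out = m)
  variants <- variant_table(model$chrom, positions, refs, alts,
                            rsid = paste0("sim", seq_len(m)))
  structure(list(haplotypes = H, freqs = pool_freqs, positions = positions,
                 variants = variants, model = model,
                 target_freqs = freqs),
            class = "haplotype_pool")
}

#' Derive a population panel from an ancestral pool
#'
#' Population allele frequencies are drawn per variant from the
#' Balding-Nichols distribution Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral frequency p (the realized frequency in the ancestral pool), so
#' that E[drifted frequency] = p and F = 0 leaves frequencies - and the
#' pool's haplotypes - unchanged. Haplotypes are resampled from the pool
#' with replacement and re-weighted towards the drifted frequencies by
#' random allele flips (0->1 with probability (p'-p)/(1-p) when the drifted
#' frequency p' exceeds p, and symmetrically otherwise), which shifts
#' marginal frequencies while degrading LD in proportion to the drift -
#' the two features that distinguish the populations downstream. Haplotype
#' pairs are summed into dosages.
#'
#' @param pool a `haplotype_pool`.
#' @param divergence_f drift parameter F in [0, 1); default from the model.
#' @param n_samples number of diploid samples.
#' @param seed RNG seed.
#' @param population label for the derived panel.
#' @return a [genotype_panel()] with attribute `target_freqs` (the drifted
#'   frequency parameters).
#' @export
derive_population <- function(pool, divergence_f = pool$model$divergence_f,
                              n_samples, seed = 1, population = "pop") {
  if (n_samples < 2) tl_stop("n_samples must be >= 2", "transloci_config")
  if (divergence_f < 0 || divergence_f >= 1) {
    tl_stop("divergence_f must be in [0, 1)", "transloci_config")
  }
  set.seed(seed)
  p <- pool$freqs
  m <- length(p)
  poly <- p > 0 & p < 1
  p_switch <- 1 - (1 - pool$model$recomb_rate)^pool$model$spacing_bp
  if (divergence_f == 0) {
    p_drift <- p
  } else {
    a <- p * (1 - divergence_f) / divergence_f
    b <- (1 - p) * (1 - divergence_f) / divergence_f
    # Balding-Nichols marginals through a locally correlated Gaussian
    # copula: each variant's drifted frequency is exactly
    # Beta(a_j, b_j)-distributed, but neighbouring variants drift together
    # the way linked variants do when whole haplotypes drift. Independent
    # per-variant draws would shear apart the LD of linked pairs far faster
    # than real between-population divergence does.
    rho <- 1 - p_switch
    e <- stats::rnorm(m)
    if (m > 1) for (j in 2:m) e[j] <- rho * e[j - 1] + sqrt(1 - rho^2) * e[j]
    p_drift <- p
    p_drift[poly] <- stats::qbeta(stats::pnorm(e[poly]), a[poly], b[poly])
    # guard against numerically fixed alleles at polymorphic sites
    p_drift[poly] <- pmin(pmax(p_drift[poly], 1e-4), 1 - 1e-4)
  }
  n_hap <- 2L * n_samples
  idx <- sample.int(nrow(pool$haplotypes), n_hap, replace = TRUE)
  H <- pool$haplotypes[idx, , drop = FALSE]
  phat <- colMeans(pool$haplotypes)
  up <- pmax(0, (p_drift - phat) / pmax(1 - phat, 1e-12))
  down <- pmax(0, (phat - p_drift) / pmax(phat, 1e-12))
  # Flip decisions are blockwise-correlated along each haplotype (the same
  # switching process as the mosaic): marginally each entry is still U(0,1),
  # so per-site frequencies hit their drifted targets, but flips co-occur in
  # contiguous segments the way drift moves haplotypes, not lone alleles.
  U <- matrix(0, nrow = n_hap, ncol = m)
  U[, 1] <- stats::runif(n_hap)
  if (m > 1) {
    for (j in 2:m) {
      sw <- stats::runif(n_hap) < p_switch
      U[, j] <- ifelse(sw, stats::runif(n_hap), U[, j - 1])
    }
  }
  flip_up <- (H == 0L) & (U < rep(up, each = n_hap))
  flip_down <- (H == 1L) & (U < rep(down, each = n_hap))
  H[flip_up] <- 1L
  H[flip_down] <- 0L
  dos <- H[seq_len(n_samples), , drop = FALSE] +
    H[n_samples + seq_len(n_samples), , drop = FALSE]
  panel <- genotype_panel(dos, pool$variants,
                          sample_ids = sprintf("%s_%05d", population, seq_len(n_samples)),
                          population = population, drop_monomorphic = FALSE)
  attr(panel, "target_freqs") <- p_drift
  panel
}

#' Simulate a quantitative phenotype with a single causal variant
#'
#' Generates y_i = beta * (x_i - 1) + eta_i where x_i is the alternate-allele
#' dosage at the causal variant and eta_i ~ N(0, sigma2) independently.
#' sigma2 = 1 puts phenotypes on the scale of a standardized trait.
#'
#' @param panel a `genotype_panel`.
#' @param beta per-allele effect size.
#' @param causal_index column index of the causal variant.
#' @param sigma2 environmental noise variance (> 0).
#' @param seed RNG seed.
#' @return numeric phenotype vector, one value per sample.
#' @export
simulate_phenotype <- function(panel, beta, causal_index, sigma2 = 1, seed = 1) {
  if (sigma2 <= 0) tl_stop("sigma2 must be > 0", "transloci_config")
  m <- ncol(panel$dosages)
  if (causal_index < 1 || causal_index > m) {
    tl_stop("causal_index outside the panel", "transloci_config")
  }
  x <- panel$dosages[, causal_index]
  if (stats::var(x) == 0) {
    tl_stop("causal variant is monomorphic in the panel", "transloci_simulation")
  }
  set.seed(seed)
  beta * (x - 1) + stats::rnorm(length(x), 0, sqrt(sigma2))
}

#' Build a paired two-cohort scenario (shared or distinct causal variants)
#'
#' Candidate causal variants are those with MAF > `maf_min` in both panels.
#' Under `kind = "shared"` one causal index is drawn uniformly and used in
#' both cohorts; under `kind = "distinct"` two indices are drawn with
#' reference-panel r-squared below `max_r2_distinct`, one per cohort.
#'
#' @param kind "shared" or "distinct".
#' @param beta effect size applied in both cohorts.
#' @param panel_ref,panel_target panels sharing variant keys.
#' @param seed RNG seed (also seeds the two phenotype draws).
#' @param max_r2_distinct LD ceiling between the two causal variants,
#'   measured in the reference panel (distinct scenarios only).
#' @param maf_min candidate minor-allele-frequency floor (default 0.05).
#' @param sigma2 environmental noise variance.
#' @return list with causal_ref, causal_target (indices), y_ref, y_target,
#'   kind, beta.
#' @export
make_scenario <- function(kind = c("shared", "distinct"), beta,
                          panel_ref, panel_target, seed = 1,
                          max_r2_distinct = 0.2, maf_min = 0.05, sigma2 = 1) {
  kind <- match.arg(kind)
  if (!identical(panel_ref$variants$id, panel_target$variants$id)) {
    tl_stop("panels must share variant keys", "transloci_config")
  }
  f1 <- panel_frequencies(panel_ref)
  f2 <- panel_frequencies(panel_target)
  cand <- which(pmin(f1, 1 - f1) > maf_min & pmin(f2, 1 - f2) > maf_min)
  if (!length(cand)) tl_stop("no candidate causal variants with sufficient MAF", "transloci_scenario")
  set.seed(seed)
  if (kind == "shared") {
    causal_ref <- cand[sample.int(length(cand), 1L)]
    causal_target <- causal_ref
  } else {
    # draw uniformly among candidates that have at least one admissible
    # partner, then the partner uniformly among admissible ones
    r2 <- suppressWarnings(
      stats::cor(panel_ref$dosages[, cand, drop = FALSE]))^2
    admissible <- !is.na(r2) & r2 < max_r2_distinct
    has_partner <- rowSums(admissible) > 0
    if (!any(has_partner)) {
      tl_stop("no candidate pair satisfies the distinct-causal LD ceiling; widen the window",
              "transloci_scenario")
    }
    i <- which(has_partner)[sample.int(sum(has_partner), 1L)]
    j <- which(admissible[i, ])
    j <- j[sample.int(length(j), 1L)]
    causal_ref <- cand[i]
    causal_target <- cand[j]
  }
  y_ref <- simulate_phenotype(panel_ref, beta, causal_ref, sigma2,
                              seed = derive_seed(seed, 101))
  y_target <- simulate_phenotype(panel_target, beta, causal_target, sigma2,
                                 seed = derive_seed(seed, 202))
  list(kind = kind, beta = beta, causal_ref = causal_ref,
       causal_target = causal_target, y_ref = y_ref, y_target = y_target)
}
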