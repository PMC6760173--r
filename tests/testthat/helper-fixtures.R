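# Shared fixture builders. Everything is generated in code; no binary files.

# small genotype panel with independent Binomial(2, p) variants
toy_panel <- function(n = 100, freqs = c(0.5, 0.3, 0.2, 0.4), seed = 1,
                      population = "toy", chrom = "1", start = 1e6L,
                      spacing = 1000L) {
  set.seed(seed)
  m <- length(freqs)
  dos <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  v <- variant_table(chrom, start + (seq_len(m) - 1L) * spacing,
                     rep(c("A", "C"), length.out = m),
                     rep(c("G", "T"), length.out = m),
                     rsid = paste0("rs", seq_len(m)))
  genotype_panel(dos, v, population = population, drop_monomorphic = FALSE)
}

# summary-stats data.frame straight from a scan of a toy panel
toy_stats <- function(n = 200, freqs = c(0.5, 0.3, 0.2), seed = 2) {
  panel <- toy_panel(n = n, freqs = freqs, seed = seed)
  y <- stats::rnorm(n)
  suppressWarnings(score_test_scan(panel, y))
}

# write a minimal VCF 4.2 text file; gt is a variants x samples character
# matrix (e.g. "0/1"), or numeric for DS
write_toy_vcf <- function(path, chrom, pos, ref, alt, gt, ids = NULL,
                          field = "GT") {
  n_samp <- ncol(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=%s,Description=\"x\">",
            field, if (field == "GT") "String" else "Float"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_len(n_samp))), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], if (is.null(ids)) "." else ids[i], ref[i],
            alt[i], ".", "PASS", ".", field, as.character(gt[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# literal, loop-everything implementation of the joint-likelihood-mapping
# statistic: the independent oracle for jlim_lambda()
jlim_lambda_bruteforce <- function(L1, L2, r1, r2, lead, theta) {
  m <- length(L1)
  if (m == 1L) return(list(lambda = NA_real_, status = "failed_single_snp"))
  lambda <- 0
  n_terms <- 0L
  for (i in seq_len(m)) {
    if (r1[i, lead]^2 < theta) next          # i must be in N^1_theta(m*)
    best <- -Inf
    for (j in seq_len(m)) {
      if (r2[i, j]^2 >= theta) next          # j must be outside N^2_theta(i)
      val <- L1[i] * L2[j]
      if (val > best) best <- val
    }
    if (!is.finite(best)) next               # empty complement: term skipped
    lambda <- lambda + L1[i] * log((L1[i] * L2[i]) / best)
    n_terms <- n_terms + 1L
  }
  if (n_terms == 0L) return(list(lambda = NA_real_, status = "failed_no_complement"))
  list(lambda = lambda, status = "ok")
}

# random correlation matrix from random dosage-like data
random_corr <- function(m, n = 50) {
  X <- matrix(stats::rnorm(n * m), nrow = n)
  stats::cor(X)
}
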