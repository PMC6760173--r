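toy_discovery <- function() {
  data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
             effect_allele = c("G", "G", "G", "G", "G"),
             other_allele = c("A", "A", "A", "A", "A"),
             beta = c(0.05, -0.04, 0.03, 0.08, 0.02),
             discovery_p = c(1e-50, 1e-40, 1e-30, 1e-20, 1e-10),
             trait = "LDL", stringsAsFactors = FALSE)
}

toy_study_stats <- function(eaf, info = NA_real_, alt = "G", ref = "A") {
  n <- length(eaf)
  data.frame(chrom = "1", pos = seq(1000L, by = 1000L, length.out = n),
             ref = ref, alt = alt, eaf = eaf,
             info = rep_len(info, n), stringsAsFactors = FALSE)
}

test_that("cross-study filters enforce the intersection rule", {
  disc <- toy_discovery()
  # study A: variant 2 rare; study B: variant 3 badly imputed, variant 4
  # carries mismatched alleles, variant 5 absent
  a <- toy_study_stats(eaf = c(0.3, 0.005, 0.4, 0.2, 0.3), info = 0.99)
  b <- toy_study_stats(eaf = c(0.3, 0.30, 0.4, 0.2, 0.3),
                       info = c(0.9, 0.9, 0.7, 0.9, 0.9))
  b$alt[4] <- "C"; b$ref[4] <- "A"
  b <- b[1:4, ]
  out <- filter_variants(disc, list(A = a, B = b))
  expect_equal(out$kept$pos, c(1000L))
  expect_setequal(out$exclusions$reason,
                  c("rare", "badly_imputed", "allele_mismatch", "absent"))

  # rare / badly imputed reasons on the stated thresholds
  expect_true("rare" %in%
    out$exclusions$reason[out$exclusions$variant ==
                            variant_id("1", 2000L, "A", "G")])
  expect_error(filter_variants(disc[2, ], list(A = a)),
               class = "transloci_validation")
})

test_that("LD pruning drops the weaker member of each correlated pair", {
  v <- data.frame(id = c("A", "B", "C"), discovery_p = c(1e-50, 1e-20, 1e-10),
                  pos = 1:3, stringsAsFactors = FALSE)
  mk_ld <- function(r2ab, r2bc, r2ac) {
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- sqrt(r2ab)
    r[2, 3] <- r[3, 2] <- sqrt(r2bc)
    r[1, 3] <- r[3, 1] <- sqrt(r2ac)
    dimnames(r) <- list(v$id, v$id)
    structure(list(r = r, ids = v$id), class = "ld_matrix")
  }
  # pair above the cap: the larger-p member goes
  out <- ld_prune(v[1:2, ], mk_ld(0.15, 0, 0))
  expect_equal(out$id, "A")
  # pair below the cap: both kept
  out2 <- ld_prune(v[1:2, ], mk_ld(0.09, 0, 0))
  expect_equal(out2$id, c("A", "B"))
  # chain A-B, B-C violating, A-C clean: keep A and C
  out3 <- ld_prune(v, mk_ld(0.2, 0.2, 0.01))
  expect_equal(out3$id, c("A", "C"))
  # the pruned set never violates the cap
  r2 <- mk_ld(0.2, 0.2, 0.01)$r[out3$id, out3$id]^2
  diag(r2) <- 0
  expect_true(all(r2 <= 0.1))
})

test_that("scores are weighted, oriented, standardized", {
  v <- variant_table("1", c(1000L, 2000L), c("A", "A"), c("G", "G"))
  dos <- rbind(c(0, 2), c(1, 1), c(2, 0), c(2, 2), c(0, 0))
  panel <- genotype_panel(dos, v, drop_monomorphic = FALSE)
  model <- grs_model(data.frame(chrom = "1", pos = c(1000L, 2000L),
                                effect_allele = c("G", "G"),
                                other_allele = c("A", "A"),
                                beta = c(0.5, -0.2)))
  score <- build_score(panel, model)
  raw <- dos %*% c(0.5, -0.2)
  expect_equal(score, as.vector(scale(raw)), tolerance = 1e-12)

  # single variant with weight 1: standardized dosage
  m1 <- grs_model(data.frame(chrom = "1", pos = 1000L, effect_allele = "G",
                             other_allele = "A", beta = 1))
  expect_equal(build_score(panel, m1), as.vector(scale(dos[, 1])))

  # orientation: effect allele = panel ref flips the dosage
  m_flip <- grs_model(data.frame(chrom = "1", pos = 1000L,
                                 effect_allele = "A", other_allele = "G",
                                 beta = 1))
  expect_equal(build_score(panel, m_flip), as.vector(scale(2 - dos[, 1])))

  # all-zero weights cannot be standardized
  m0 <- grs_model(data.frame(chrom = "1", pos = c(1000L, 2000L),
                             effect_allele = c("G", "G"),
                             other_allele = c("A", "A"), beta = c(0, 0)))
  expect_error(build_score(panel, m0), class = "transloci_degenerate")

  # missing model variants are an error, not a silent skip
  m_miss <- grs_model(data.frame(chrom = "1", pos = 9999L,
                                 effect_allele = "G", other_allele = "A",
                                 beta = 1))
  expect_error(build_score(panel, m_miss), class = "transloci_validation")
})

test_that("score associations equal Pearson correlations and calibrate", {
  set.seed(110)
  s <- rnorm(500)
  # slope on standardized inputs equals cor() to numerical precision
  y <- 0.4 * s + rnorm(500)
  a <- associate_score(s, y)
  expect_equal(a$r, cor(s, y), tolerance = 1e-10)
  expect_equal(a$n, 500)

  self <- associate_score(s, s)
  expect_equal(self$r, 1, tolerance = 1e-12)

  # null calibration over seeds
  ps <- vapply(1:200, function(k) {
    set.seed(k)
    associate_score(rnorm(300), rnorm(300))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  expect_error(associate_score(s, y[-1]), class = "transloci_validation")
})

test_that("cross-trait association matrix has the expected shape", {
  set.seed(111)
  base <- rnorm(400)
  scores <- list(HDL = rnorm(400), TG = scale(base)[, 1])
  phenos <- list(HDL = rnorm(400), TG = scale(base + rnorm(400, 0, 0.5))[, 1])
  m <- associate_score_matrix(scores, phenos)
  expect_equal(nrow(m), 4L)
  tg_tg <- m[m$score_trait == "TG" & m$outcome_trait == "TG", ]
  expect_true(tg_tg$significant)
})

test_that("end-to-end score recovery matches the variance-explained closed form", {
  # a score built from known weights explaining 8% of variance recovers
  # r = sqrt(0.08) at n = 10000
  set.seed(112)
  n <- 10000
  freqs <- runif(15, 0.1, 0.9)
  panel <- toy_panel(n = n, freqs = freqs, seed = 113)
  w <- runif(15, -0.1, 0.1)
  model <- grs_model(data.frame(chrom = panel$variants$chrom,
                                pos = panel$variants$pos,
                                effect_allele = panel$variants$alt,
                                other_allele = panel$variants$ref,
                                beta = w))
  g <- build_score(panel, model)   # standardized genetic value
  h2 <- 0.08
  y <- sqrt(h2) * g + rnorm(n, 0, sqrt(1 - h2))
  a <- associate_score(g, y)
  se_r <- sqrt((1 - h2) / n)
  expect_lt(abs(a$r - sqrt(h2)), 3 * se_r)
})
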