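test_that("locus dedup keeps the strongest variant per window", {
  hits <- data.frame(chrom = "1", pos = c(100000L, 120000L),
                     trait = "TG", discovery_p = c(1e-120, 1e-110))
  out <- dedup_loci(hits, window_bp = 50000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 100000L)
  expect_true(out$major)

  single <- data.frame(chrom = "2", pos = 5e6, trait = "HDL",
                       discovery_p = 1e-50)
  out1 <- dedup_loci(single)
  expect_equal(out1$pos, single$pos)
  expect_false(out1$major)

  # same position, different traits: both kept
  two <- data.frame(chrom = "1", pos = c(1e6, 1e6), trait = c("HDL", "TG"),
                    discovery_p = c(1e-150, 1e-140))
  expect_equal(nrow(dedup_loci(two)), 2L)
})

test_that("credible sets use a strict r2 threshold and always hold the lead", {
  panel <- toy_panel(n = 500, freqs = rep(0.4, 4), seed = 50)
  # LD to the lead (variant 1): r2 of 0.61, just below 0.6, and 0.59 - the
  # strict threshold keeps only the first (the boundary value sits a hair
  # under 0.6 to dodge floating-point round-off of sqrt)
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- sqrt(0.61)
  r[1, 3] <- r[3, 1] <- sqrt(0.6 - 1e-9)
  r[1, 4] <- r[4, 1] <- sqrt(0.59)
  ld <- structure(list(r = r, ids = panel$variants$id), class = "ld_matrix")
  dimnames(ld$r) <- list(ld$ids, ld$ids)
  locus <- list(id = panel$variants$id[1], trait = "HDL", major = TRUE,
                chrom = "1", pos = panel$variants$pos[1])
  cs <- build_credible_set(locus, ld, r2_threshold = 0.6)
  expect_setequal(cs$members, panel$variants$id[1:2])  # only the 0.61

  # no correlated variants: members = lead
  lone <- structure(list(r = diag(4), ids = ld$ids), class = "ld_matrix")
  dimnames(lone$r) <- list(ld$ids, ld$ids)
  expect_equal(build_credible_set(locus, lone)$members, locus$id)

  # r2_threshold = 0 pulls in everything with r2 > 0
  cs0 <- build_credible_set(locus, ld, r2_threshold = 0)
  expect_setequal(cs0$members, panel$variants$id)

  expect_error(build_credible_set(list(id = "nope"), ld),
               class = "transloci_validation")
})

test_that("empirical threshold calibration matches the closed form", {
  # 1000 windows of 50 Kb over 50 variants each, uniform null p-values:
  # P(min p < 1e-3) = 1 - 0.999^50
  set.seed(60)
  m <- 50051
  stats <- data.frame(chrom = "1", pos = seq(1L, by = 1000L, length.out = m),
                      p = runif(m))
  res <- empirical_threshold(stats, n_windows = 1000, width_bp = 50000, seed = 3)
  expected <- 1 - 0.999^50
  mc_se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(res$proportion - expected), 3 * mc_se)

  # all p = 1: proportion 0, usable threshold
  stats$p <- 1
  res1 <- empirical_threshold(stats, n_windows = 200, width_bp = 50000, seed = 4)
  expect_equal(res1$proportion, 0)
  expect_true(res1$pass)

  # identical draw under the same seed
  stats$p <- runif(m)
  a <- empirical_threshold(stats, 200, 50000, seed = 9)
  b <- empirical_threshold(stats, 200, 50000, seed = 9)
  expect_identical(a$min_p, b$min_p)

  # insufficient coverage errors
  expect_error(empirical_threshold(stats[1:100, ], 1000, 50000, seed = 1),
               class = "transloci_validation")
})

make_target <- function(ids, chrom, pos, p) {
  data.frame(id = ids, chrom = chrom, pos = pos, p = p,
             stringsAsFactors = FALSE)
}

test_that("locus classification follows the category rules exactly", {
  locus <- list(id = "1:1000000:A:G", trait = "TG", major = TRUE,
                chrom = "1", pos = 1000000L)
  cs <- structure(list(locus = locus,
                       members = c("1:1000000:A:G", "1:1000500:C:T")),
                  class = "credible_set")
  # member below threshold: credible_set_hit
  t1 <- make_target(cs$members, "1", c(1000000L, 1000500L), c(0.5, 5e-4))
  expect_equal(classify_locus(cs, t1)$category, "credible_set_hit")

  # members above, region variant below: region_hit
  t2 <- make_target(c(cs$members, "1:1010000:A:G"), "1",
                    c(1000000L, 1000500L, 1010000L), c(0.5, 0.2, 1e-5))
  expect_equal(classify_locus(cs, t2)$category, "region_hit")

  # everything above threshold: not_significant
  t3 <- make_target(c(cs$members, "1:1010000:A:G"), "1",
                    c(1000000L, 1000500L, 1010000L), c(0.5, 0.2, 0.002))
  expect_equal(classify_locus(cs, t3)$category, "not_significant")

  # no target variants anywhere near: indeterminate
  t4 <- make_target("9:5000000:A:G", "9", 5000000L, 0.01)
  expect_equal(classify_locus(cs, t4)$category, "indeterminate")

  # strictness: p exactly at the threshold does not count
  t5 <- make_target(cs$members, "1", c(1000000L, 1000500L), c(1e-3, 1e-3))
  expect_equal(classify_locus(cs, t5)$category, "not_significant")

  # monotone in the threshold: lowering it never upgrades a call
  cat_levels <- c(not_significant = 0, region_hit = 1, credible_set_hit = 2)
  for (thr in c(1e-2, 1e-3, 1e-4, 1e-6)) {
    c_hi <- classify_locus(cs, t2, p_threshold = thr)$category
    c_lo <- classify_locus(cs, t2, p_threshold = thr / 10)$category
    expect_lte(cat_levels[[c_lo]], cat_levels[[c_hi]])
  }
})

test_that("rate tables stratify and sum to 100 within rounding", {
  calls <- data.frame(
    trait = c(rep("TG", 19), "HDL", "HDL", "HDL"),
    major = c(rep(TRUE, 19), FALSE, FALSE, FALSE),
    category = c(rep("credible_set_hit", 18), "not_significant",
                 "credible_set_hit", "region_hit", "not_significant"))
  tab <- rate_table(calls)
  tg <- tab[tab$trait == "TG" & tab$major, ]
  expect_equal(round(tg$pct_credible_set_hit, 1), 94.7)   # 18 / 19
  hdl <- tab[tab$trait == "HDL" & !tab$major, ]
  expect_equal(unlist(hdl[, c("pct_not_significant", "pct_region_hit",
                              "pct_credible_set_hit")]),
               c(100 / 3, 100 / 3, 100 / 3), ignore_attr = TRUE)
  sums <- rowSums(tab[, c("pct_not_significant", "pct_region_hit",
                          "pct_credible_set_hit")])
  expect_true(all(abs(sums - 100) < 0.1))

  all_ns <- data.frame(trait = "LDL", major = TRUE,
                       category = rep("not_significant", 5))
  expect_equal(rate_table(all_ns)$pct_not_significant, 100)
})

test_that("classification categories partition any classified input", {
  set.seed(70)
  panel <- toy_panel(n = 300, freqs = runif(30, 0.1, 0.9), seed = 71)
  target <- suppressWarnings(score_test_scan(panel, rnorm(300)))
  ld <- ld_matrix(panel)
  cats <- vapply(seq_len(20), function(i) {
    locus <- list(id = panel$variants$id[i], trait = "HDL", major = TRUE,
                  chrom = panel$variants$chrom[i], pos = panel$variants$pos[i])
    cs <- build_credible_set(locus, ld)
    classify_locus(cs, target)$category
  }, character(1))
  expect_true(all(cats %in% c("credible_set_hit", "region_hit",
                              "not_significant", "indeterminate")))
})
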