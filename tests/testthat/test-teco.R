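test_that("single-causal likelihood: closed form, symmetry, MVN oracle", {
  # all z equal: uniform
  expect_equal(single_causal_likelihood(c(2, 2, 2)), rep(1 / 3, 3))

  # direct evaluation of the normalized form
  L <- single_causal_likelihood(c(3, 0, 0))
  expect_equal(L, exp(c(4.5, 0, 0)) / sum(exp(c(4.5, 0, 0))), tolerance = 1e-12)
  expect_equal(sum(L), 1)

  # huge z must not overflow
  expect_false(any(is.nan(single_causal_likelihood(c(60, 10, 0)))))

  # brute-force profile-likelihood oracle: maximize the MVN density of
  # z ~ N(lambda * r_.i, R) over lambda on a grid, per candidate i
  set.seed(80)
  for (rep in 1:5) {
    m <- 5
    R <- random_corr(m, n = 40)
    R <- (R + diag(1e-6, m)) / (1 + 1e-6)
    z <- rnorm(m, 0, 2)
    Rinv <- solve(R)
    logL <- vapply(seq_len(m), function(i) {
      ri <- R[, i]
      neg <- function(lam) {
        d <- z - lam * ri
        0.5 * drop(t(d) %*% Rinv %*% d)
      }
      -stats::optimize(neg, c(-100, 100), tol = 1e-12)$objective
    }, numeric(1))
    oracle <- exp(logL - max(logL))
    oracle <- oracle / sum(oracle)
    expect_equal(single_causal_likelihood(z), oracle, tolerance = 1e-6)
  }
})

test_that("lambda statistic: worked 3-SNP example and sign properties", {
  r_shared <- diag(3)
  r_shared[1, 2] <- r_shared[2, 1] <- sqrt(0.9)
  r_shared[1, 3] <- r_shared[3, 1] <- sqrt(0.1)
  r_shared[2, 3] <- r_shared[3, 2] <- sqrt(0.1)
  L1 <- c(0.7, 0.2, 0.1)
  L2 <- c(0.6, 0.3, 0.1)
  res <- jlim_lambda(L1, L2, r_shared, r_shared, lead = 1, theta = 0.8)
  expect_equal(res$status, "ok")
  # hand enumeration: sum over i in {1, 2}; complement {3} for both
  expect_equal(res$lambda, 0.7 * log(0.6 / 0.1) + 0.2 * log(0.3 / 0.1),
               tolerance = 1e-12)
  expect_equal(round(res$lambda, 4), 1.474)

  # target mass on the lead's LD class: positive; on an uncorrelated
  # variant: negative
  conc_on_lead <- c(0.98, 0.01, 0.01)
  conc_away <- c(0.01, 0.01, 0.98)
  expect_gt(jlim_lambda(L1, conc_on_lead, r_shared, r_shared, 1)$lambda, 0)
  expect_lt(jlim_lambda(L1, conc_away, r_shared, r_shared, 1)$lambda, 0)

  # degenerate statuses
  expect_equal(jlim_lambda(1, 1, matrix(1), matrix(1), 1)$status,
               "failed_single_snp")
  all_linked <- matrix(1, 3, 3)
  expect_equal(jlim_lambda(L1, L2, r_shared, all_linked, 1)$status,
               "failed_no_complement")
})

test_that("lambda equals the literal loop oracle on random instances", {
  set.seed(81)
  n_checked <- 0L
  for (rep in seq_len(300)) {
    m <- sample(2:6, 1)
    r1 <- random_corr(m, n = 25)
    r2 <- random_corr(m, n = 25)
    L1 <- single_causal_likelihood(rnorm(m, 0, 2))
    L2 <- single_causal_likelihood(rnorm(m, 0, 2))
    lead <- sample.int(m, 1)
    theta <- runif(1, 0.4, 0.95)
    got <- jlim_lambda(L1, L2, r1, r2, lead, theta)
    want <- jlim_lambda_bruteforce(L1, L2, r1, r2, lead, theta)
    expect_identical(got$status, want$status)
    if (got$status == "ok") {
      expect_equal(got$lambda, want$lambda, tolerance = 1e-10)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("batched z-space lambda agrees with the likelihood-space form", {
  set.seed(82)
  m <- 12
  r1 <- random_corr(m, n = 60)
  r2 <- random_corr(m, n = 60)
  z1 <- rnorm(m, 0, 3)
  L1 <- single_causal_likelihood(z1)
  Z2 <- matrix(rnorm(m * 7, 0, 2), nrow = m)
  lead <- which.max(z1^2)
  batch <- transloci:::jlim_lambda_batch(L1, Z2^2, r1[, lead]^2, r2^2, 0.8)
  for (b in seq_len(ncol(Z2))) {
    single <- jlim_lambda(L1, single_causal_likelihood(Z2[, b]),
                          r1, r2, lead, 0.8)
    expect_equal(batch$lambda[b], single$lambda, tolerance = 1e-10)
  }
})

test_that("permutation p-values: bounds, determinism, null uniformity", {
  model <- population_model(n_variants = 25)
  pool <- simulate_ancestral_haplotypes(model, seed = 90)
  ref <- derive_population(pool, 0, 1500, seed = 91)
  tgt <- derive_population(pool, 0.1, 400, seed = 92)
  keep <- apply(ref$dosages, 2, var) > 0 & apply(tgt$dosages, 2, var) > 0
  ids <- ref$variants$id[keep]
  ref <- subset_panel(ref, ids); tgt <- subset_panel(tgt, ids)

  y_ref <- simulate_phenotype(ref, 0.3, causal_index = 3, seed = 93)
  z1 <- score_test_scan(ref, (y_ref - mean(y_ref)) / sd(y_ref))$z
  ld1 <- ld_matrix(ref)
  lead <- which.max(z1^2)

  y_tgt <- simulate_phenotype(tgt, 0.3, causal_index = 3, seed = 94)
  inp <- coloc_input(z1, ld1, tgt, y_tgt, lead)
  res <- permutation_p(inp, B = 200, seed = 1)
  expect_s3_class(res, "coloc_result")
  expect_gte(res$p_jlim, 1 / 201)
  expect_lte(res$p_jlim, 1)
  # shared strong signal should colocalize
  expect_lt(res$p_jlim, 0.05)

  res2 <- permutation_p(inp, B = 200, seed = 1)
  expect_identical(res$p_jlim, res2$p_jlim)

  # null target phenotype: p approximately uniform over repeated draws
  set.seed(95)
  ps <- vapply(1:60, function(k) {
    y0 <- rnorm(nrow(tgt$dosages))
    permutation_p(coloc_input(z1, ld1, tgt, y0, lead), B = 100,
                  seed = 1000 + k)$p_jlim
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("p_jlim is invariant to relabelling of non-lead variants", {
  model <- population_model(n_variants = 15)
  pool <- simulate_ancestral_haplotypes(model, seed = 96)
  ref <- derive_population(pool, 0, 800, seed = 97)
  tgt <- derive_population(pool, 0.05, 300, seed = 98)
  keep <- apply(ref$dosages, 2, var) > 0 & apply(tgt$dosages, 2, var) > 0
  ids <- ref$variants$id[keep]
  ref <- subset_panel(ref, ids); tgt <- subset_panel(tgt, ids)
  y_ref <- simulate_phenotype(ref, 0.25, 2, seed = 99)
  z1 <- score_test_scan(ref, scale(y_ref)[, 1])$z
  ld1 <- ld_matrix(ref)
  y_tgt <- simulate_phenotype(tgt, 0.25, 2, seed = 100)
  lead <- which.max(z1^2)
  base <- permutation_p(coloc_input(z1, ld1, tgt, y_tgt, lead), B = 150, seed = 5)

  perm <- sample(length(ids))
  tgt_p <- subset_panel(tgt, ids[perm])
  ld1_p <- structure(list(r = ld1$r[perm, perm], ids = ld1$ids[perm]),
                     class = "ld_matrix")
  res_p <- permutation_p(coloc_input(z1[perm], ld1_p, tgt_p, y_tgt,
                                     which(perm == lead)), B = 150, seed = 5)
  expect_equal(res_p$lambda_stat, base$lambda_stat, tolerance = 1e-10)
  expect_equal(res_p$p_jlim, base$p_jlim, tolerance = 1e-12)
})

test_that("run_coloc excludes the MHC and guards small windows", {
  mhc_locus <- list(chrom = "6", pos = 30000000L)
  out <- run_coloc(mhc_locus, ref_stats = NULL, ref_ld_panel = NULL,
                   target_panel = NULL, target_phenotype = NULL)
  expect_equal(out$status, "excluded_mhc")
  # a locus on chr6 beyond the window half-width past the MHC end runs
  model <- population_model(n_variants = 30, chrom = "6",
                            start_bp = mhc_region()$end + 30000L)
  pool <- simulate_ancestral_haplotypes(model, seed = 101)
  ref <- derive_population(pool, 0, 1000, seed = 102)
  tgt <- derive_population(pool, 0.05, 300, seed = 103)
  keep <- apply(ref$dosages, 2, var) > 0 & apply(tgt$dosages, 2, var) > 0
  ids <- ref$variants$id[keep]
  ref <- subset_panel(ref, ids); tgt <- subset_panel(tgt, ids)
  y_ref <- simulate_phenotype(ref, 0.4, 5, seed = 104)
  stats <- score_test_scan(ref, scale(y_ref)[, 1])
  y_tgt <- simulate_phenotype(tgt, 0.4, 5, seed = 105)

  lead_row <- which.max(stats$z^2)
  locus <- list(chrom = stats$chrom[lead_row], pos = stats$pos[lead_row])
  res <- run_coloc(locus, stats, ref, tgt, y_tgt, B = 100, seed = 6)
  expect_equal(res$status, "ok")

  # fewer than 5 shared variants fails with a diagnostic
  few <- subset_panel(tgt, ids[1:3])
  expect_message(
    res2 <- run_coloc(locus, stats[1:3, ], ref, few, y_tgt, B = 100, seed = 6),
    "shared variant")
  expect_equal(res2$status, "failed_insufficient_variants")
})
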