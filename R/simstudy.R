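#' Configuration for the colocalization simulation study
#'
#' Bundles the effect-size grid, replicate counts, permutation budget and
#' synthetic-population settings used by [estimate_type1()] and
#' [estimate_power()]. Defaults follow the calibration protocol: effect
#' sizes 0.10-0.25 on a standardized trait (sigma2 = 1), 400 replicates per
#' cell, 200 permutations, 100-variant 50 Kb windows, a reference cohort of
#' 5,000 and a target cohort of 2,000 samples, per-population drift F = 0.1.
#'
#' @param beta_grid positive effect sizes to test.
#' @param n_replicates replicates per cell (>= 50 for reported cells).
#' @param B permutations per replicate.
#' @param alpha significance level for p_jlim (default 0.05).
#' @param n_ref,n_target per-cohort sample sizes.
#' @param n_variants variants per locus window.
#' @param n_windows number of distinct window panels generated; replicates
#'   cycle over them (causal draws stay random per replicate, mirroring
#'   repeated draws over fixed cohort genotypes).
#' @param divergence_f Balding-Nichols drift applied to each population.
#' @param theta LD threshold of the colocalization statistic.
#' @param max_r2_distinct LD ceiling between the two causal variants in
#'   distinct-causal scenarios (reference panel r-squared).
#' @param maf_min causal-candidate MAF floor (default 0.05).
#' @param sigma2 environmental noise variance (default 1).
#' @param seed master seed; replicate streams are derived from it.
#' @return list of class `sim_study_config`.
#' @export
sim_study_config <- function(beta_grid = c(0.10, 0.15, 0.20, 0.25),
                             n_replicates = 400, B = 200, alpha = 0.05,
                             n_ref = 5000, n_target = 2000,
                             n_variants = 100, n_windows = 20,
                             divergence_f = 0.1, theta = 0.8,
                             max_r2_distinct = 0.2, maf_min = 0.05,
                             sigma2 = 1, seed = 1) {
  if (any(beta_grid < 0)) tl_stop("beta_grid must be non-negative", "transloci_config")
  if (n_replicates < 50) tl_stop("n_replicates must be >= 50 for reported cells", "transloci_config")
  structure(list(beta_grid = beta_grid, n_replicates = n_replicates, B = B,
                 alpha = alpha, n_ref = n_ref, n_target = n_target,
                 n_variants = n_variants, n_windows = n_windows,
                 divergence_f = divergence_f, theta = theta,
                 max_r2_distinct = max_r2_distinct, maf_min = maf_min,
                 sigma2 = sigma2, seed = seed),
            class = "sim_study_config")
}

# internal: generate the window panels once and precompute everything the
# per-replicate engine needs (standardized dosages, squared LD, candidate
# causal variants). Variants monomorphic in either cohort are dropped from
# both so keys stay aligned.
make_sim_windows <- function(config) {
  lapply(seq_len(config$n_windows), function(w) {
    for (try in 0:20) {
      win <- make_one_window(config, w, try)
      # a window can come out (nearly) monomorphic when the whole region
      # drifts to extreme frequency; redraw rather than waste replicates
      if (length(win$candidates) >= 10) return(win)
    }
    tl_stop("could not generate a polymorphic window in 20 tries", "transloci_simulation")
  })
}

make_one_window <- function(config, w, try) {
    model <- population_model(n_variants = config$n_variants,
                              divergence_f = config$divergence_f)
    pool <- simulate_ancestral_haplotypes(
      model, seed = derive_seed(config$seed, 10000 + w + 511 * try))
    # the reference cohort is held at the ancestral LD (the discovery-study
    # population); only the target population drifts, so divergence_f is the
    # divergence between the two cohorts
    ref <- derive_population(pool, 0, config$n_ref,
                             seed = derive_seed(config$seed, 20000 + w + 511 * try),
                             population = "ref")
    tgt <- derive_population(pool, config$divergence_f, config$n_target,
                             seed = derive_seed(config$seed, 30000 + w + 511 * try),
                             population = "target")
    poly <- matrixVar(ref$dosages) > 0 & matrixVar(tgt$dosages) > 0
    Xr <- ref$dosages[, poly, drop = FALSE]
    Xt <- tgt$dosages[, poly, drop = FALSE]
    xs_ref <- standardize_columns(Xr)
    xs_tgt <- standardize_columns(Xt)
    r1 <- crossprod(xs_ref) / (nrow(Xr) - 1)
    r2 <- crossprod(xs_tgt) / (nrow(Xt) - 1)
    f1 <- colMeans(Xr) / 2
    f2 <- colMeans(Xt) / 2
    cand <- which(pmin(f1, 1 - f1) > config$maf_min &
                    pmin(f2, 1 - f2) > config$maf_min)
    list(X_ref = Xr, X_tgt = Xt, xs_ref = xs_ref, xs_tgt = xs_tgt,
         r1sq = r1^2, r2sq = r2^2, candidates = cand)
}

# internal: one simulation replicate. Draws the causal variant(s), simulates
# both phenotypes, scans the reference cohort, and runs the permutation test
# on the target cohort. Returns a one-row data.frame.
sim_replicate <- function(win, kind, beta, config, seed) {
  set.seed(seed)
  cand <- win$candidates
  if (!length(cand)) {
    return(data.frame(p_jlim = NA_real_, lambda = NA_real_,
                      status = "scenario_failed", causal_ref = NA_integer_,
                      causal_target = NA_integer_))
  }
  if (kind == "shared") {
    causal_ref <- cand[sample.int(length(cand), 1L)]
    causal_target <- causal_ref
  } else {
    admissible <- win$r1sq[cand, cand, drop = FALSE] < config$max_r2_distinct
    has_partner <- rowSums(admissible) > 0
    if (!any(has_partner)) {
      return(data.frame(p_jlim = NA_real_, lambda = NA_real_,
                        status = "scenario_failed",
                        causal_ref = NA_integer_, causal_target = NA_integer_))
    }
    i <- which(has_partner)[sample.int(sum(has_partner), 1L)]
    j <- which(admissible[i, ])
    j <- j[sample.int(length(j), 1L)]
    causal_ref <- cand[i]
    causal_target <- cand[j]
  }
  n_ref <- nrow(win$X_ref)
  n_tgt <- nrow(win$X_tgt)
  sd_eta <- sqrt(config$sigma2)
  y_ref <- beta * (win$X_ref[, causal_ref] - 1) + stats::rnorm(n_ref, 0, sd_eta)
  y_tgt <- beta * (win$X_tgt[, causal_target] - 1) + stats::rnorm(n_tgt, 0, sd_eta)
  ys_ref <- (y_ref - mean(y_ref)) / stats::sd(y_ref)
  z1 <- as.vector(crossprod(win$xs_ref, ys_ref)) * (sqrt(n_ref) / (n_ref - 1))
  lead <- which.max(z1^2)
  res <- coloc_perm_core(win$xs_tgt, y_tgt, z1, win$r1sq, win$r2sq,
                         lead, config$theta, config$B,
                         seed = derive_seed(seed, 7))
  data.frame(p_jlim = res$p_jlim, lambda = res$lambda_stat,
             status = res$status, causal_ref = causal_ref,
             causal_target = causal_target)
}

# internal: run n_replicates of one scenario cell over pre-built windows
run_sim_cell <- function(windows, kind, beta, config, cell_tag) {
  logs <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    win <- windows[[(r - 1L) %% length(windows) + 1L]]
    row <- sim_replicate(win, kind, beta, config,
                         seed = derive_seed(config$seed, cell_tag * 100000 + r))
    row$replicate <- r
    row$window <- (r - 1L) %% length(windows) + 1L
    logs[[r]] <- row
  }
  log <- do.call(rbind, logs)
  failed <- log$status != "ok"
  if (mean(failed) > 0.2) {
    tl_stop(sprintf("%.0f%% of replicates failed (statuses: %s); inspect the scenario settings",
                    100 * mean(failed),
                    paste(unique(log$status[failed]), collapse = ", ")),
            "transloci_simulation")
  }
  log
}

#' Estimate the type-I error of trans-ethnic colocalization
#'
#' Runs distinct-causal replicates (the two cohorts carry different causal
#' variants, separated in reference LD) and reports the fraction rejected at
#' `alpha`, with a Wilson 95% confidence interval. Failed-status replicates
#' are excluded from the denominator and reported separately.
#'
#' @param config a [sim_study_config()].
#' @param beta effect size used in both cohorts (default: largest grid value).
#' @param windows optional pre-built windows (reused across calls).
#' @return list with rate, ci (Wilson), n_tested, n_failed, alpha and the
#'   per-replicate `log`.
#' @export
estimate_type1 <- function(config, beta = max(config$beta_grid),
                           windows = NULL) {
  if (is.null(windows)) windows <- make_sim_windows(config)
  log <- run_sim_cell(windows, "distinct", beta, config, cell_tag = 1L)
  ok <- log$status == "ok"
  rej <- sum(log$p_jlim[ok] < config$alpha)
  ci <- wilson_ci(rej, sum(ok))
  list(rate = unname(ci["estimate"]), ci = ci, n_tested = sum(ok),
       n_failed = sum(!ok), alpha = config$alpha, beta = beta, log = log)
}

#' Estimate the power of trans-ethnic colocalization over an effect-size grid
#'
#' Runs shared-causal replicates for every beta in the grid and reports the
#' fraction rejected at `alpha` per cell, with Wilson 95% intervals.
#'
#' @param config a [sim_study_config()].
#' @param windows optional pre-built windows (reused across calls).
#' @return list with `table` (beta, power, lower, upper, n_tested, n_failed)
#'   and the per-replicate `log`.
#' @export
estimate_power <- function(config, windows = NULL) {
  if (is.null(windows)) windows <- make_sim_windows(config)
  rows <- list(); logs <- list()
  for (k in seq_along(config$beta_grid)) {
    beta <- config$beta_grid[k]
    log <- run_sim_cell(windows, "shared", beta, config, cell_tag = 100L + k)
    ok <- log$status == "ok"
    ci <- wilson_ci(sum(log$p_jlim[ok] < config$alpha), sum(ok))
    rows[[k]] <- data.frame(beta = beta, power = unname(ci["estimate"]),
                            lower = unname(ci["lower"]),
                            upper = unname(ci["upper"]),
                            n_tested = sum(ok), n_failed = sum(!ok))
    log$beta <- beta
    logs[[k]] <- log
  }
  list(table = do.call(rbind, rows), log = do.call(rbind, logs),
       alpha = config$alpha)
}

#' Downsample a genotype panel
#'
#' Uniform sample of `n` samples without replacement (sample order is
#' normalized to the original ordering). Variant keys are unchanged;
#' variants monomorphic after downsampling are counted in a message.
#'
#' @param panel a `genotype_panel`.
#' @param n target sample count (n <= panel size).
#' @param seed RNG seed.
#' @return a `genotype_panel` of `n` samples.
#' @export
downsample_panel <- function(panel, n, seed = 1) {
  n_all <- nrow(panel$dosages)
  if (n > n_all) tl_stop("cannot downsample beyond the panel size", "transloci_config")
  set.seed(seed)
  idx <- sort(sample.int(n_all, n))
  out <- subset_panel(panel, sample_idx = idx)
  mono <- sum(matrixVar(out$dosages) == 0)
  if (mono > 0) {
    message(sprintf("%d variant(s) monomorphic after downsampling", mono))
  }
  out
}
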