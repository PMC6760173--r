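# transloci

Tools for asking whether GWAS loci discovered in one ancestry group are
driven by the same causal variants in another — the *transferability*
question that decides whether genetic risk prediction built on
European-ancestry discovery cohorts carries over to East Asian or African
populations. The package was built around blood lipids (HDL, LDL,
triglycerides), where discovery panels of hundreds of thousands of
Europeans meet target cohorts with very different allele frequencies and
linkage disequilibrium (LD).

Lookup replication fails here for structural reasons: the discovery lead is
usually only a proxy of the causal variant, and how good a proxy it is
depends on population-specific LD. `transloci` implements the three
complementary strategies that get around this, plus the synthetic data
needed to calibrate them:

* **Credible-set reproducibility** — a locus reproduces in a target study
  if any variant correlated with the lead at r² > 0.6 (in an
  ancestry-matched reference panel) is associated at p < 10⁻³ by a score
  test; a ±25 Kb region lookup and an empirical random-window check of the
  threshold back this up.
* **Trans-ethnic colocalization** — under a single causal variant the
  per-variant causal likelihood reduces to L(i) ∝ exp(z²ᵢ/2); the statistic

  Λ = Σ_{i∈N¹θ(m*)} L₁(i) · log [ L₁(i)L₂(i) / max_{j∉N²θ(i)} L₁(i)L₂(j) ]

  contrasts the target cohort's likelihood mass inside versus outside the
  lead variant m*'s LD neighborhood (Nθ = variants at r² ≥ θ, θ = 0.8),
  with significance from permuting the target phenotype (add-one
  estimator). Reference cohorts need only summary statistics; targets need
  raw genotypes.
* **Weighted genetic risk scores** — discovery-β-weighted allele scores
  after cross-study presence/MAF/imputation filters and r² > 0.1 pruning,
  standardized so regression slopes are score-biomarker correlations.
* **A two-population genotype generator** — founder-mosaic haplotypes with
  Balding–Nichols drift (frequency divergence F), preserving realistic LD
  decay and cross-population LD conservation, driving type-I error and
  power experiments for the colocalization test.

## Worked example

Simulate a discovery cohort (n = 5000) and a diverged target cohort
(n = 2000, F = 0.1) sharing one causal variant (β = 0.25) in a 50 Kb
window, then run the full locus assessment:

```r
library(transloci)

model <- population_model()                    # 100 SNPs, 50 Kb window
pool  <- simulate_ancestral_haplotypes(model, seed = 11)
eur   <- derive_population(pool, 0,   5000, seed = 12, population = "discovery")
afr   <- derive_population(pool, 0.1, 2000, seed = 13, population = "target")
keep  <- apply(eur$dosages, 2, var) > 0 & apply(afr$dosages, 2, var) > 0
eur   <- subset_panel(eur, eur$variants$id[keep])
afr   <- subset_panel(afr, afr$variants$id[keep])

sc   <- make_scenario("shared", beta = 0.25, eur, afr, seed = 14)
disc <- score_test_scan(eur, prepare_phenotype(sc$y_ref))
i    <- which.max(disc$z^2)
disc[i, c("id", "z", "p", "eaf")]
#>             id        z            p    eaf
#>  1:1004000:A:G 11.20182 3.994604e-29 0.2298
```

The discovery lead is a major signal (z = 11.2). Build its credible set
from discovery-panel LD and classify reproducibility in the target:

```r
locus <- list(id = disc$id[i], chrom = disc$chrom[i], pos = disc$pos[i],
              trait = "LDL", major = TRUE)
cs <- build_credible_set(locus, ld_matrix(eur))
length(cs$members)
#> [1] 10
tstats <- score_test_scan(afr, prepare_phenotype(sc$y_target))
classify_locus(cs, tstats)[, c("category", "best_p_credible")]
#>          category best_p_credible
#>  credible_set_hit    4.272623e-14
```

A credible-set member is associated in the target at p ≈ 4e-14: the locus
reproduces. Colocalization confirms the two signals share a causal variant:

```r
run_coloc(locus, disc, eur, afr, prepare_phenotype(sc$y_target),
          B = 1000, seed = 15)
#> coloc_result: lambda = 8.42, p_jlim = 0.000999 (B = 1000, status = ok)
```

Λ > 0 (target likelihood mass inside the lead's LD class) with the smallest
p the add-one estimator allows at B = 1000. Finally, the packaged BMI
lookup for lipid loci with clear transferability evidence reproduces the
pleiotropy contrast at the Bonferroni threshold 0.05/21 = 0.0024:

```r
bmi <- load_bmi_lookup()
thr <- bonferroni_threshold(0.05, nrow(bmi))$rounded
count_pleiotropy(data.frame(rsid = bmi$rsid, bmi_p = bmi$bmi_p),
                 ifelse(bmi$transferable == "No", "non_transferable",
                        "transferable"), thr)
#>              label  n n_bmi_associated
#> 1 non_transferable 14               10
#> 2     transferable  7                0
```

Ten of fourteen non-transferable loci are BMI-pleiotropic; none of the
seven transferable ones are.

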