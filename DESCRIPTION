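Package: transloci
Title: Transferability of GWAS Loci Across Ancestry Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether genetic associations discovered in one
    ancestry group are shared by another. Implements score-test association
    scans, rank-based inverse normal transformation and Friedewald LDL
    derivation, credible-set based reproducibility classification of
    established loci, trans-ethnic colocalization via a joint-likelihood
    mapping statistic with a permutation null, weighted genetic risk scores
    with LD pruning, transferable versus non-transferable locus labelling
    with BMI pleiotropy counts, and a two-population synthetic genotype
    generator (founder-mosaic haplotypes with Balding-Nichols drift) used to
    calibrate type-I error and power of the colocalization test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
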