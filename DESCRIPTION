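Package: targetmr
Title: Two-Step Drug-Target Mendelian Randomization with Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-sample, two-step Mendelian randomization pipeline for
    drug-target repurposing from GWAS and eQTL summary statistics:
    cis-eQTL instrument selection (cis-window, MAF and p-value thresholds,
    greedy LD pruning, cross-tissue minimal-p selection), allele
    harmonization with palindromic-SNP resolution and LD-proxy
    substitution, Wald-ratio and fixed-effect inverse-variance-weighted
    estimation with Bonferroni gating, confidence-interval/odds-ratio
    reconstruction helpers, a weighted running-sum gene-set enrichment
    statistic with a permutation null, and a summary-level simulator of
    the full SNP -> expression -> biomarker -> outcome causal chain for
    validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
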