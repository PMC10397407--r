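---
title: "Two-step drug-target Mendelian randomization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step drug-target Mendelian randomization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The design

Drug-target Mendelian randomization (MR) asks whether pharmacological
modulation of a protein target is likely to affect a disease outcome, using
genetics as a stand-in for the drug. `targetmr` implements the two-step
variant of this design for lipid-lowering drug targets and bone phenotypes:

1. **Step 1 — target expression to biomarker.** For each drug-target gene,
   a cis-eQTL SNP serves as an instrument for the gene's expression, and a
   Wald/IVW estimate measures the causal effect of a 1-SD increase in
   expression on LDL-cholesterol (in LDL-C SDs).
2. **Step 2 — biomarker to outcome.** Instruments of genes that pass a
   Bonferroni gate in step 1 are carried forward, now instrumenting LDL-C,
   to estimate the effect of a 1-SD change in LDL-C on bone mineral density
   (forearm, femoral neck, lumbar spine; outcome SDs) and on fracture
   (log-odds, reported as an odds ratio).

Both steps are two-sample MR: all inputs are GWAS/eQTL summary statistics
(per-SNP effect, SE, p, allele pair, effect-allele frequency, sample size).
The identifying assumptions are the usual instrumental-variable ones —
relevance, no confounding of the instrument, and no pathway to the outcome
other than through the exposure. The pipeline tests relevance explicitly
(instrument p-value threshold) and assumes the other two.

## Instrument selection

`filter_cis()`, `ld_prune()` and `best_across_tissues()` implement the
selection rules, with defaults in `selection_config()`:

| parameter | default | meaning |
|---|---|---|
| `cis_window_bp` | 1,000,000 | cis window on either side of the gene body (bp), boundary inclusive |
| `maf_min` | 0.01 | minor-allele frequency, strict `>` |
| `p_instrument_max` | 1e-5 | eQTL p-value, strict `<` |
| `ld_prune_r2` | 0.1 | kept instruments pairwise `r² <` this bound |
| `alpha` | 0.05 | family-wise level for both Bonferroni gates |

Where the convention was open we fixed it once and test it: thresholds are
strict inequalities, the window boundary is inclusive, pruning is greedy by
ascending p-value (standard "clumping"; ties by lexicographic SNP id), and
cross-tissue selection (minimal p, ties by lexicographic tissue then SNP)
happens after per-tissue filtering and pruning. Selection is therefore
deterministic and invariant to input row order.

The step-1 gate divides `alpha` by the total number of candidate
instrument variants tested across genes and tissues (the analogue of a
threshold like 0.05/4,283); the step-2 gate divides by the number of
(gene, outcome) tests actually run (e.g. 0.05/9).

## Harmonization and proxies

`harmonize()` aligns the outcome record onto the exposure record's effect
allele: identity, swapped labels (sign flip), strand complement, or — for
palindromic A/T and C/G SNPs — orientation by allele frequency. A
palindromic pair is resolvable only when both frequencies are outside
`0.5 ± 0.08`; the 0.08 margin is the conventional cautious default and is
configurable. Records lacking a frequency cannot be oriented and are
dropped. Every drop carries exactly one machine-readable reason
(`ambiguous_palindrome`, `incompatible_alleles`, `no_proxy`).

When an instrument is absent from an outcome panel, `find_proxy()`
substitutes the panel SNP with the highest `r² ≥ 0.8`. Only unsigned `r²`
is available, so the proxy's orientation relative to the instrument is
inferred from allele frequency (high-LD pairs have nearly equal minor-allele
frequencies); proxies whose frequency sits inside the palindrome window are
unusable and the pair is excluded. Proxy substitution keeps the
instrument's exposure statistics and uses the proxy's outcome statistics —
the standard convention — which attenuates the step-2 estimate by roughly
the genotype correlation `r`; with `r² ≥ 0.8` the attenuation is at most
about 10% and we accept it rather than attempt an unidentified correction.

## Estimators

For exposure effect `bx` (SE `sx`) and outcome effect `by` (SE `sy`):

* Wald ratio: `beta = by / bx`. Default SE `sy / |bx|` (first order,
  exposure uncertainty ignored) — the convention under which fixed-effect
  IVW reduces exactly to the single-SNP case. The full delta-method SE
  `sqrt(sy²/bx² + by²·sx²/bx⁴)` is available via `se_method = "delta"`.
* Fixed-effect IVW over instruments `j`:
  `beta = Σ bx_j by_j / sy_j² / Σ bx_j² / sy_j²`,
  `se = (Σ bx_j² / sy_j²)^(-1/2)` — the intercept-free weighted regression
  of outcome on exposure effects.
* `finalize_estimate()` attaches a normal-theory two-sided p-value and a
  95% CI using `z = 1.959964` (the same constant is used by
  `se_from_ci()`, so CI→SE→CI round trips are exact to print precision);
  binary outcomes are exponentiated to the odds-ratio scale.

The first-order SE is the package default because it matches how IVW is
conventionally reported. It is accurate when the exposure sample is large
relative to the outcome sample. In the validation setting below the
*eQTL* panel (n = 1,000) is far smaller than the biomarker GWAS
(n = 170,000), the exposure-side variance dominates, and first-order
intervals undercover by construction; the delta-method flag exists for
exactly this regime and is what the validation and acceptance runs use.

We deliberately compute no heterogeneity or pleiotropy statistics
(Cochran's Q, MR-Egger, weighted median): with one instrument per gene they
are undefined, and the design this package mirrors reports none.

## The synthetic-data generator

`simulate_summary_stats()` generates every input table under a known causal
chain so the full pipeline can be validated against truth. Observed effects
are simulated directly at the summary level:
`beta_hat = beta_true + N(0, se²)` with the standardized-trait SE
`se = 1/sqrt(2·n·eaf·(1−eaf))`. For a causal SNP with expression effect
`b`: the exposure-GWAS truth is `θ₁·b` and the outcome truth `θ₂·θ₁·b`
(zero for designated null genes). Defaults emulate the study conditions the
pipeline is designed for: `n_eqtl = 1000`, `n_gwas_exposure = 170000`,
`n_gwas_outcome = 30000`, `θ₁ = −0.2`, and per-outcome `θ₂` taken from the
published two-step estimates (FA −2.36, FN −1.4, LS −2.07 outcome-SD per
LDL-C SD; fracture 1.24 log-odds per LDL-C SD).

Design choices worth knowing:

* **LD blocks.** 20 SNPs per gene in blocks of 5 with within-block
  `r² = 0.9`: block mates are simultaneously prunable (`r² ≥ 0.1`) and
  proxy-eligible (`r² ≥ 0.8`), so both mechanisms are exercised. True
  marginal effects of block mates are `r·b` and sampling noise is
  correlated at `r = √r²` within a block, as LD implies.
* **Consistent labelling.** All SNPs in a block share an allele-labelling
  side, so positive within-block LD, effect signs and allele frequencies
  stay mutually consistent — the property frequency-based proxy
  orientation relies on in real data.
* **Strong planted instruments.** Causal effect magnitudes are
  `eqtl_effect_min + |N(0, eqtl_effect_sd²)|` (defaults 0.5 and 1.0
  expression-SD per allele), i.e. top-cis-eQTL-strength signals that clear
  the `p < 1e-5` selection threshold decisively. Effects near the
  threshold would make selection and estimation interact (winner's curse)
  and validation would measure that interaction rather than estimator
  calibration.
* **Correlated tissues.** eQTL tissues share truth and have noise
  correlation 0.8 (`tissue_noise_cor`), reflecting tissue panels drawn
  from largely the same donors. With independent noise, minimal-p
  cross-tissue selection would be a pure noise race and would bias the
  selected effect upward.
* **Harmonization stress.** A configurable fraction of outcome rows is
  emitted with swapped allele labels (default 20%), and a fraction of SNPs
  is withheld from each outcome panel (default 5%) to force proxy lookup.
  Palindromic allele pairs arise naturally (~1/3 of SNPs).
* **Binary outcome.** Fracture is simulated on the log-odds scale with the
  same Gaussian machinery and reported as an odds ratio.

What the generator does **not** emulate: individual-level genotypes,
population structure, sample overlap between exposure and outcome GWAS,
horizontal pleiotropy, winner's-curse-affected weak instruments, and
realistic genome-wide LD. Passing validation therefore shows the
estimators and plumbing are correct under the stated model, not that the
design's identifying assumptions hold in any real data set.

## Validation results computed by the test-suite

With 600 genes (1/6 null), default sample sizes and delta-method SEs, the
pipeline's 95% CIs cover `θ₁` and `θ₂` for 93–95% of causal genes across
seeds, and null genes essentially never pass the step-1 gate (expected
false passes ≈ 0.007 per run). Proxy-substituted pairs undercover
(≈ 0.7) because of the `r` attenuation discussed above; they are ~4% of
gene-outcome pairs at the default missingness. These checks run in the
acceptance test and script; the problem sizes (600 genes, 4 outcomes,
~12,000 SNPs) were chosen as the smallest that give the coverage estimate
a standard error near 0.01.

The published result tables this pipeline mirrors are shipped in
`inst/extdata/reference_mr_estimates.tsv` and are used purely for
internal-consistency arithmetic: recovering the SE from a printed 95% CI
(`se_from_ci()`), recomputing the two-sided p, and reproducing a printed
odds ratio as the exponentiated log-CI midpoint. Rows printed with ~3
decimals reconstruct their p-values within 15% relative error; rows with
extreme significance (|z| ≳ 6) cannot — the printed CI's rounding error
overwhelms the tail probability — so for those only the |z| ordering is
asserted. One row (femoral-neck BMD, printed p = 0.001) carries a single
significant figure, and its own rounding exceeds any percentage band;
it is checked at its printed precision instead.

## Numerical conventions

* `z₀.₉₇₅ = 1.959964` everywhere a 95% interval is built or inverted.
* P-values are clamped to `(ε, 1]`; betas/SEs are written with 15
  significant digits so file round trips are exact to ≥ 12.
* The GSEA enrichment score is the signed extremum of the running sum; an
  exact tie between the positive and negative extremes resolves to the
  positive one, with a 1e-9 relative tolerance so the choice is stable
  under floating-point accumulation order.
* Unicode minus signs and scientific notation are accepted on input;
  output is plain ASCII.

## The GSEA stage

`enrichment_score()` is the weighted Kolmogorov–Smirnov running-sum
statistic (hit increments `|score|^p / Σ_hits |score|^p`, miss decrements
`1/(N−N_hits)`), with `weight_p = 1` as the classic default.
`permutation_pvalue()` uses a gene-label permutation null — the only null
available when the input is a ranked profile rather than an expression
matrix — and `bh_adjust()` applies Benjamini–Hochberg step-up adjustment
across sets. Disease gene sets are assembled by case-normalized union
across source lists (`assemble_gene_set()`), mirroring how an
osteoporosis set would be pooled from several disease databases. Real
drug-perturbation profiles are deliberately not bundled (external and
version-dependent); synthetic ranked profiles with planted enriched sets
exercise the machinery structurally.

## Known limitations

* Proxy orientation uses allele frequency only; in data sets where LD sign
  information (D') is available, that would be strictly better.
* The Bonferroni gates treat all instrument variants as independent tests;
  correlated instruments make the gate conservative.
* One-sample overlap between eQTL selection and step-1 estimation (the
  same eQTL data selects and estimates) is inherent to the design this
  package mirrors; with weak instruments it would bias step-1 toward the
  null. The generator's strong-instrument defaults keep this negligible in
  validation, and real applications should check instrument F-statistics.
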