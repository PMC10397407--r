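# Summary-level simulator of the causal chain
#   SNP -> gene expression -> LDL-C-like biomarker -> outcome(s)
# used to validate the whole two-step MR pipeline against known truth.
#
# Statistics are simulated directly at the summary level: the observed
# effect of SNP j on a standardized trait with sample size n is
#   beta_hat_j = beta_true_j + e_j,  e_j ~ N(0, se_j^2),
#   se_j = 1 / sqrt(2 * n * eaf_j * (1 - eaf_j)),
# the standard large-sample SE of a per-allele effect on a unit-variance
# trait. SNPs are laid out in LD blocks; block mates have genotype
# correlation sqrt(within_block_r2), which induces (i) attenuated true
# marginal effects (r * b) for non-causal block mates of a causal SNP and
# (ii) correlated sampling noise, so LD pruning and proxy lookup matter.

#' Simulation parameters
#'
#' Bundles and validates every knob of the synthetic summary-statistics
#' generator. The defaults emulate the study conditions the pipeline is
#' designed for: an eQTL panel of ~1,000 donors, a lipid GWAS of 170,000
#' subjects, outcome GWAS of ~30,000, a first-step causal effect
#' `theta1 = -0.2` (biomarker SD per expression SD) and second-step effects
#' per outcome taken from the published two-step estimates (binary outcome
#' on the log-odds scale).
#'
#' @param n_genes Number of target genes to simulate.
#' @param snps_per_gene Cis SNPs per gene.
#' @param ld_block_size SNPs per LD block (last block may be shorter).
#' @param within_block_r2 r-squared between SNPs in the same block, in
#'   \[0, 1).
#' @param theta1 True causal effect of expression on the biomarker
#'   (biomarker SD per expression SD). Null genes carry no pass-through.
#' @param theta2_by_outcome Named numeric vector of true causal effects of
#'   the biomarker on each outcome (outcome SD, or log-odds for binary
#'   outcomes, per biomarker SD).
#' @param n_eqtl,n_gwas_exposure,n_gwas_outcome Sample sizes of the eQTL
#'   panel, biomarker GWAS and outcome GWAS (all >= 10).
#' @param eqtl_effect_sd Scale of the causal SNP-on-expression effects
#'   (expression SD per allele): effect magnitudes are
#'   `eqtl_effect_min + |N(0, eqtl_effect_sd^2)|` with a random sign.
#' @param eqtl_effect_min Minimum causal-effect magnitude (default 0.5).
#'   The floor makes every planted instrument a *top-cis-eQTL*-strength
#'   signal, comfortably clearing the `p < 1e-5` selection threshold at
#'   `n_eqtl = 1000`, so pipeline validation measures estimator calibration
#'   rather than detection at the threshold (where winner's curse would
#'   dominate any estimator).
#' @param null_gene_fraction Fraction of genes whose eQTL signal has zero
#'   pass-through to the biomarker (`theta1` contribution 0).
#' @param maf_range Range (low, high) of block minor-allele frequencies,
#'   a subset of (0, 0.5].
#' @param n_tissues Number of eQTL tissues; tissues share the same true
#'   effects.
#' @param tissue_noise_cor Correlation of eQTL sampling noise across
#'   tissues (default 0.8): tissue panels drawn from largely the same
#'   donors have strongly correlated effect estimates, which keeps
#'   cross-tissue minimal-p selection from being a pure noise race.
#' @param causal_per_gene Number of causal eQTL SNPs per gene (default 1,
#'   matching a per-gene single-instrument structure).
#' @param outcome_missing_fraction Fraction of SNPs absent from each
#'   outcome GWAS panel (exercises proxy substitution).
#' @param allele_flip_fraction Fraction of outcome GWAS rows written with
#'   swapped allele labels and sign-flipped beta (exercises harmonization).
#' @param seed Integer seed; all output is deterministic given the seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 36,
                       snps_per_gene = 20,
                       ld_block_size = 5,
                       within_block_r2 = 0.9,
                       theta1 = -0.2,
                       theta2_by_outcome = c(FA_BMD = -2.36, FN_BMD = -1.4,
                                             LS_BMD = -2.07, fracture = 1.24),
                       n_eqtl = 1000,
                       n_gwas_exposure = 170000,
                       n_gwas_outcome = 30000,
                       eqtl_effect_sd = 1.0,
                       eqtl_effect_min = 0.5,
                       null_gene_fraction = 0.25,
                       maf_range = c(0.1, 0.5),
                       n_tissues = 2,
                       tissue_noise_cor = 0.8,
                       causal_per_gene = 1,
                       outcome_missing_fraction = 0.05,
                       allele_flip_fraction = 0.2,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            snps_per_gene = as.integer(snps_per_gene),
            ld_block_size = as.integer(ld_block_size),
            within_block_r2 = within_block_r2,
            theta1 = theta1,
            theta2_by_outcome = theta2_by_outcome,
            n_eqtl = n_eqtl,
            n_gwas_exposure = n_gwas_exposure,
            n_gwas_outcome = n_gwas_outcome,
            eqtl_effect_sd = eqtl_effect_sd,
            eqtl_effect_min = eqtl_effect_min,
            null_gene_fraction = null_gene_fraction,
            maf_range = maf_range,
            n_tissues = as.integer(n_tissues),
            tissue_noise_cor = tissue_noise_cor,
            causal_per_gene = as.integer(causal_per_gene),
            outcome_missing_fraction = outcome_missing_fraction,
            allele_flip_fraction = allele_flip_fraction,
            seed = as.integer(seed))
  if (p$n_genes < 1 || p$snps_per_gene < 1 || p$ld_block_size < 1)
    abort_tmr("n_genes, snps_per_gene, ld_block_size must be >= 1",
              "targetmr_param_error")
  if (p$within_block_r2 < 0 || p$within_block_r2 >= 1)
    abort_tmr("within_block_r2 must be in [0, 1)", "targetmr_param_error")
  if (any(c(p$n_eqtl, p$n_gwas_exposure, p$n_gwas_outcome) < 10))
    abort_tmr("all sample sizes must be >= 10", "targetmr_param_error")
  if (is.null(names(p$theta2_by_outcome)) ||
      any(!nzchar(names(p$theta2_by_outcome))))
    abort_tmr("theta2_by_outcome must be a named vector",
              "targetmr_param_error")
  if (length(p$maf_range) != 2 || p$maf_range[1] >= p$maf_range[2] ||
      p$maf_range[1] <= 0 || p$maf_range[2] > 0.5)
    abort_tmr("maf_range must be (low, high) within (0, 0.5]",
              "targetmr_param_error")
  if (p$tissue_noise_cor < 0 || p$tissue_noise_cor >= 1)
    abort_tmr("tissue_noise_cor must be in [0, 1)", "targetmr_param_error")
  if (p$eqtl_effect_sd < 0 || p$eqtl_effect_min < 0)
    abort_tmr("eqtl_effect_sd and eqtl_effect_min must be >= 0",
              "targetmr_param_error")
  if (p$null_gene_fraction < 0 || p$null_gene_fraction > 1)
    abort_tmr("null_gene_fraction must be in [0, 1]", "targetmr_param_error")
  if (p$causal_per_gene < 1 || p$causal_per_gene > p$snps_per_gene)
    abort_tmr("causal_per_gene must be in [1, snps_per_gene]",
              "targetmr_param_error")
  class(p) <- "sim_params"
  p
}

# Deterministic genome layout (no RNG): gene names, loci, SNP ids,
# positions and LD-block assignments. Genes sit on their own 4-Mb islands
# so cis windows never overlap.
#' @keywords internal
sim_layout <- function(params) {
  ng <- params$n_genes
  ns <- params$snps_per_gene
  gi <- seq_len(ng)
  gene <- sprintf("G%04d", gi)
  chrom <- as.character(((gi - 1L) %% 22L) + 1L)
  start <- 1e6 + ((gi - 1L) %/% 22L) * 4e6
  end <- start + 5e4
  loci <- data.frame(gene = gene, chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  gidx <- rep(gi, each = ns)
  j <- rep(seq_len(ns), times = ng)
  block_in_gene <- ((j - 1L) %/% params$ld_block_size) + 1L
  nblocks <- ceiling(ns / params$ld_block_size)
  snps <- data.frame(
    gene = gene[gidx],
    gene_idx = gidx,
    snp_id = sprintf("rs%d", gidx * 1000L + j),
    chrom = chrom[gidx],
    pos = start[gidx] - 4e5 + (j - 1L) * 4e4,
    block = (gidx - 1L) * nblocks + block_in_gene,
    stringsAsFactors = FALSE
  )
  list(loci = loci, snps = snps)
}

#' Simulate the pairwise LD table
#'
#' SNPs are partitioned into blocks of `ld_block_size`; every within-block
#' pair receives `r2 = within_block_r2`; cross-block pairs are absent
#' (r-squared 0 by convention). Deterministic given the seed (the block
#' structure itself involves no randomness).
#'
#' @param params A [sim_params()] object.
#' @return An [ld_table()].
#' @export
simulate_ld <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  snps <- sim_layout(params)$snps
  by_block <- split(snps$snp_id, snps$block)
  pairs <- lapply(by_block, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
               r2 = params$within_block_r2, stringsAsFactors = FALSE)
  })
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  entries <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  rownames(entries) <- NULL
  ld_table(entries)
}

#' Simulate eQTL, exposure-GWAS and outcome-GWAS summary statistics
#'
#' Generates every table the two-step pipeline consumes, under a known
#' causal chain. For a SNP with true per-allele expression effect `b`, the
#' true biomarker-GWAS effect is `theta1 * b` and the true outcome effect
#' is `theta2 * theta1 * b` (zero pass-through for null genes). Observed
#' effects are truth plus noise with the analytic standardized-trait SE for
#' the respective sample size; noise is correlated within LD blocks.
#' P-values are two-sided normal; `eaf` is drawn from `maf_range` at the
#' block level (block mates share nearly equal frequencies, as high LD
#' implies). A configurable fraction of outcome rows is emitted with
#' swapped allele labels (sign-flipped beta, complemented eaf) and a
#' fraction of SNPs is withheld from each outcome panel.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `mr_simulation` with elements `eqtl` (eQTL
#'   records across tissues), `exposure_gwas`, `outcome_gwas` (named list of
#'   data frames), `loci`, `targets` (a synthetic drug-target table with one
#'   entry per gene), and `truth` (a `simulation_truth` list holding the
#'   generating parameters, per-gene causal SNPs/effects and per-SNP true
#'   marginal expression effects).
#' @export
simulate_summary_stats <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  lay <- sim_layout(params)
  snps <- lay$snps
  nsnp <- nrow(snps)
  ng <- params$n_genes
  r_ld <- sqrt(params$within_block_r2)

  # null genes
  n_null <- round(ng * params$null_gene_fraction)
  null_idx <- if (n_null > 0) sort(sample.int(ng, n_null)) else integer(0)
  is_null <- seq_len(ng) %in% null_idx

  # block-level allele frequencies; SNP maf jitters around its block's
  blocks <- sort(unique(snps$block))
  block_maf <- stats::runif(length(blocks), params$maf_range[1],
                            params$maf_range[2])
  block_of <- match(snps$block, blocks)
  maf <- block_maf[block_of] + stats::rnorm(nsnp, 0, 0.01)
  maf <- pmin(pmax(maf, params$maf_range[1]), params$maf_range[2])
  # The canonical effect allele is the minor or major allele at random,
  # chosen per *block*: true marginal effects within a block are written
  # on a shared orientation with positive LD, so block mates must also
  # share a labelling side for effect sign and allele frequency to stay
  # mutually consistent (frequency-based proxy orientation relies on it).
  block_side <- stats::runif(length(blocks)) < 0.5
  eaf <- ifelse(block_side[block_of], maf, 1 - maf)

  # allele pair per SNP (ordered, distinct; palindromic pairs possible)
  ea <- sample(VALID_BASES, nsnp, replace = TRUE)
  oa <- vapply(ea, function(x) sample(setdiff(VALID_BASES, x), 1), "")

  # causal SNPs and effects per gene
  snps_of_gene <- split(seq_len(nsnp), snps$gene_idx)
  causal_snp <- vector("list", ng)
  causal_beta <- vector("list", ng)
  expr_true <- numeric(nsnp)
  for (g in seq_len(ng)) {
    rows <- snps_of_gene[[g]]
    pick <- rows[sample.int(length(rows), params$causal_per_gene)]
    b <- sample(c(-1, 1), params$causal_per_gene, replace = TRUE) *
      (params$eqtl_effect_min +
         abs(stats::rnorm(params$causal_per_gene, 0, params$eqtl_effect_sd)))
    causal_snp[[g]] <- snps$snp_id[pick]
    causal_beta[[g]] <- b
    for (k in seq_along(pick)) {
      same_block <- rows[snps$block[rows] == snps$block[pick[k]]]
      expr_true[same_block] <- expr_true[same_block] + r_ld * b[k]
      expr_true[pick[k]] <- expr_true[pick[k]] + (1 - r_ld) * b[k]
    }
  }

  # block-correlated sampling noise: corr(beta_hat_i, beta_hat_j) equals
  # the genotype correlation sqrt(r2), via a one-factor block model
  a <- params$within_block_r2^(1 / 4)
  draw_unit_noise <- function() {
    shared <- stats::rnorm(length(blocks))
    a * shared[block_of] + sqrt(1 - a^2) * stats::rnorm(nsnp)
  }
  make_rows <- function(beta_true, n, unit_noise = draw_unit_noise()) {
    se <- 1 / sqrt(2 * n * eaf * (1 - eaf))
    beta <- beta_true + se * unit_noise
    data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
               pos = snps$pos, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta, se = se,
               pvalue = two_sided_p(beta / se), n = n,
               stringsAsFactors = FALSE)
  }

  # eQTL records: tissues share the truth, and their sampling noise is
  # correlated at tissue_noise_cor (shared donors across tissue panels)
  rho <- params$tissue_noise_cor
  common <- draw_unit_noise()
  eqtl <- do.call(rbind, lapply(seq_len(params$n_tissues), function(t) {
    un <- sqrt(rho) * common + sqrt(1 - rho) * draw_unit_noise()
    df <- make_rows(expr_true, params$n_eqtl, unit_noise = un)
    df$gene <- snps$gene
    df$tissue <- sprintf("tissue_%02d", t)
    df
  }))
  rownames(eqtl) <- NULL

  pass <- ifelse(rep(is_null, each = params$snps_per_gene), 0, 1)
  exposure_true <- params$theta1 * expr_true * pass
  exposure_gwas <- make_rows(exposure_true, params$n_gwas_exposure)

  outcome_gwas <- lapply(params$theta2_by_outcome, function(theta2) {
    df <- make_rows(theta2 * exposure_true, params$n_gwas_outcome)
    # swapped-allele rows: same association, opposite labelling
    flip <- stats::runif(nsnp) < params$allele_flip_fraction
    tmp <- df$effect_allele[flip]
    df$effect_allele[flip] <- df$other_allele[flip]
    df$other_allele[flip] <- tmp
    df$beta[flip] <- -df$beta[flip]
    df$eaf[flip] <- 1 - df$eaf[flip]
    keep <- stats::runif(nsnp) >= params$outcome_missing_fraction
    df[keep, , drop = FALSE]
  })
  names(outcome_gwas) <- names(params$theta2_by_outcome)

  targets <- data.frame(
    drug_class = "synthetic",
    substance = paste0("compound_", lay$loci$gene),
    drugbank_id = sprintf("DB%05d", seq_len(ng)),
    genes = I(as.list(lay$loci$gene)),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    params = params,
    theta1 = params$theta1,
    theta2_by_outcome = params$theta2_by_outcome,
    genes = data.frame(
      gene = lay$loci$gene,
      is_null = is_null,
      causal_snps = vapply(causal_snp, paste, "", collapse = ";"),
      causal_betas = vapply(causal_beta, function(b)
        paste(fmt_num(b), collapse = ";"), ""),
      stringsAsFactors = FALSE),
    snps = data.frame(gene = snps$gene, snp_id = snps$snp_id,
                      block = snps$block, eaf = eaf,
                      expr_beta_true = expr_true,
                      exposure_beta_true = exposure_true,
                      stringsAsFactors = FALSE)
  ), class = "simulation_truth")

  structure(list(eqtl = eqtl, exposure_gwas = exposure_gwas,
                 outcome_gwas = outcome_gwas, loci = lay$loci,
                 targets = targets, truth = truth),
            class = "mr_simulation")
}
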