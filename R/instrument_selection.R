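# Instrument-selection rules for the first MR step: cis-window
# restriction, MAF and p-value thresholds, greedy LD pruning
# ("clumping"), cross-tissue minimal-p selection, and the Bonferroni
# significance threshold. Thresholds are strict inequalities
# (MAF > maf_min, p < p_instrument_max, r^2 < ld_prune_r2); the cis-window
# boundary is inclusive.

#' Instrument-selection configuration
#'
#' @param cis_window_bp Half-width of the cis window around the gene body,
#'   in bp (default 1 Mb on either side).
#' @param maf_min Minimum minor-allele frequency, exclusive (default 1%).
#' @param p_instrument_max Maximum eQTL p-value, exclusive (default 1e-5).
#' @param ld_prune_r2 Pruning threshold: kept SNPs are pairwise
#'   `r2 < ld_prune_r2` (default 0.1).
#' @param alpha Family-wise significance level for Bonferroni gating
#'   (default 0.05).
#' @return A validated list of class `selection_config`.
#' @export
selection_config <- function(cis_window_bp = 1e6,
                             maf_min = 0.01,
                             p_instrument_max = 1e-5,
                             ld_prune_r2 = 0.1,
                             alpha = 0.05) {
  cfg <- list(cis_window_bp = cis_window_bp, maf_min = maf_min,
              p_instrument_max = p_instrument_max, ld_prune_r2 = ld_prune_r2,
              alpha = alpha)
  if (cfg$cis_window_bp < 0)
    abort_tmr("cis_window_bp must be >= 0", "targetmr_param_error")
  if (cfg$maf_min < 0 || cfg$maf_min >= 0.5)
    abort_tmr("maf_min must be in [0, 0.5)", "targetmr_param_error")
  if (cfg$p_instrument_max <= 0 || cfg$p_instrument_max > 1)
    abort_tmr("p_instrument_max must be in (0, 1]", "targetmr_param_error")
  if (cfg$ld_prune_r2 <= 0 || cfg$ld_prune_r2 > 1)
    abort_tmr("ld_prune_r2 must be in (0, 1]", "targetmr_param_error")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    abort_tmr("alpha must be in (0, 1)", "targetmr_param_error")
  class(cfg) <- "selection_config"
  cfg
}

#' Cis-window, MAF and p-value filter
#'
#' Keeps eQTL records on the locus chromosome with position inside
#' `[start - cis_window_bp, end + cis_window_bp]` (boundaries inclusive),
#' minor-allele frequency `min(eaf, 1 - eaf) > maf_min` and
#' `pvalue < p_instrument_max`. Input order is preserved. Records on a
#' different chromosome than the locus are dropped with a warning rather
#' than an error (they are out of scope, not malformed).
#'
#' @param records eQTL records (`data.frame`), all for `locus$gene`.
#' @param locus A one-row gene locus (`gene`, `chrom`, `start`, `end`).
#' @param cfg A [selection_config()].
#' @return The filtered `data.frame`.
#' @export
filter_cis <- function(records, locus, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  if (nrow(records) == 0) return(records)
  if (!all(records$gene == locus$gene))
    abort_tmr("filter_cis: records do not all belong to the locus gene",
              "targetmr_param_error")
  mismatch <- records$chrom != locus$chrom
  if (any(mismatch)) {
    warning(sprintf("filter_cis: dropping %d record(s) for %s on a different chromosome than the locus",
                    sum(mismatch), locus$gene), call. = FALSE)
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  keep <- !mismatch &
    records$pos >= locus$start - cfg$cis_window_bp &
    records$pos <= locus$end + cfg$cis_window_bp &
    maf > cfg$maf_min &
    records$pvalue < cfg$p_instrument_max
  records[keep, , drop = FALSE]
}

#' Greedy LD pruning (clumping)
#'
#' Repeatedly takes the remaining record with the smallest p-value (ties
#' broken by lexicographically smaller `snp_id`) and discards every
#' remaining record with `r2 >= ld_prune_r2` against it. The output is a
#' maximal greedy independent set: kept SNPs are pairwise
#' `r2 < ld_prune_r2`, and every discarded SNP violates the bound against
#' some kept SNP. Idempotent, and invariant to input row order.
#'
#' @param records eQTL records (`data.frame`) with `snp_id` and `pvalue`.
#' @param ld An [ld_table()].
#' @param cfg A [selection_config()].
#' @return The pruned `data.frame` (rows of `records`, in selection order).
#' @export
ld_prune <- function(records, ld, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  if (nrow(records) <= 1) return(records)
  ord <- order(records$pvalue, records$snp_id)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining) > 0) {
    head_i <- remaining[1]
    kept <- c(kept, head_i)
    rest <- remaining[-1]
    if (length(rest)) {
      r2 <- ld_r2(ld, records$snp_id[rest], rep(records$snp_id[head_i],
                                                length(rest)))
      remaining <- rest[r2 < cfg$ld_prune_r2]
    } else {
      remaining <- rest
    }
  }
  records[kept, , drop = FALSE]
}

#' Cross-tissue minimal-p instrument selection
#'
#' From candidate instruments for one gene (possibly spanning several
#' tissues), returns the record with the smallest eQTL p-value; exact ties
#' are broken by the lexicographically smaller (tissue, snp_id) pair, so
#' selection is deterministic and stable under input permutation.
#'
#' @param instruments Candidate eQTL records (`data.frame`) for one gene.
#' @return The single selected row.
#' @export
best_across_tissues <- function(instruments) {
  if (is.null(instruments) || nrow(instruments) == 0)
    abort_tmr("gene has no eligible instrument", "targetmr_no_instrument")
  if (length(unique(instruments$gene)) > 1)
    abort_tmr("best_across_tissues: records span multiple genes",
              "targetmr_param_error")
  tissue <- if ("tissue" %in% names(instruments)) instruments$tissue else ""
  ord <- order(instruments$pvalue, tissue, instruments$snp_id)
  instruments[ord[1], , drop = FALSE]
}

#' Bonferroni significance threshold
#'
#' Returns `alpha / m` at full precision; reporting rounds to 2
#' significant figures where a printed threshold is quoted.
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != floor(m))
    abort_tmr("bonferroni_threshold: m must be an integer >= 1",
              "targetmr_param_error")
  if (alpha <= 0 || alpha >= 1)
    abort_tmr("bonferroni_threshold: alpha must be in (0, 1)",
              "targetmr_param_error")
  alpha / m
}
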