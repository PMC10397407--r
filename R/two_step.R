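# Orchestration of the two-step drug-target MR design:
#   step 1: drug-target gene expression (cis-eQTL instruments) -> biomarker
#   step 2: biomarker -> outcomes, carrying forward only the instruments of
#           genes that pass the step-1 Bonferroni gate.

#' Run the two-step drug-target MR pipeline
#'
#' Per target gene: select instrument(s) from the eQTL records (cis-window,
#' MAF and p thresholds, greedy LD pruning per tissue, cross-tissue
#' minimal-p selection), harmonize them against the exposure (biomarker)
#' GWAS, and estimate the expression -> biomarker effect (Wald ratio for a
#' single instrument, fixed-effect IVW for several). Genes passing the
#' step-1 Bonferroni gate (`alpha / m1`, where `m1` is the total number of
#' candidate instrument variants tested) carry their instrument SNPs into
#' step 2, where the biomarker is the exposure: per outcome, the instrument
#' is looked up in the outcome GWAS (with LD-proxy substitution at
#' `r2 >= proxy_r2_min` when absent), harmonized, estimated and gated at
#' `alpha / m2` (`m2` = number of step-2 tests actually run). Exclusions
#' (no eligible instrument, no proxy) and harmonization drops are recorded
#' with machine-readable reasons. Output ordering is deterministic
#' (gene, outcome).
#'
#' @param eqtl eQTL summary statistics (`data.frame`, eQTL schema).
#' @param loci Gene loci (`data.frame`: `gene`, `chrom`, `start`, `end`).
#' @param targets Drug-target table (`data.frame` with list-column `genes`,
#'   as from [read_target_table()]); the gene universe is the union of its
#'   gene lists. Substances with an empty gene list are logged as excluded.
#' @param exposure_gwas Biomarker GWAS summary statistics (`data.frame`).
#' @param outcome_gwas_map Named list of outcome GWAS `data.frame`s.
#' @param ld An [ld_table()] (used for pruning and proxy search).
#' @param cfg A [selection_config()].
#' @param instruments_per_gene `"1"` (default: the single cross-tissue
#'   minimal-p instrument, one Wald ratio per gene) or `"all"` (all pruned
#'   instruments from the winning tissue, pooled by IVW).
#' @param se_method Wald-ratio SE mode, `"first_order"` or `"delta"`
#'   (see [wald_ratio()]); IVW pooling always uses the fixed-effect SE.
#' @param proxy_r2_min Minimum r-squared for proxy substitution
#'   (default 0.8).
#' @param palindrome_eaf_margin See [harmonize()].
#' @param binary_outcomes Names of outcomes on the log-odds scale, reported
#'   also as odds ratios (default `"fracture"`).
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `two_step_result`: a list with `step1` and
#'   `step2` result `data.frame`s, `exclusions` and `drops` logs, the test
#'   counts `m1`/`m2` and the two Bonferroni thresholds. Use
#'   `as.data.frame()` or [write_results()] to flatten.
#' @export
run_two_step <- function(eqtl, loci, targets, exposure_gwas,
                         outcome_gwas_map, ld,
                         cfg = selection_config(),
                         instruments_per_gene = c("1", "all"),
                         se_method = c("first_order", "delta"),
                         proxy_r2_min = 0.8,
                         palindrome_eaf_margin = 0.08,
                         binary_outcomes = "fracture",
                         ci_level = 0.95) {
  instruments_per_gene <- match.arg(instruments_per_gene)
  se_method <- match.arg(se_method)
  stopifnot(inherits(ld, "ld_table"), inherits(cfg, "selection_config"))
  if (is.null(names(outcome_gwas_map)) || any(!nzchar(names(outcome_gwas_map))))
    abort_tmr("outcome_gwas_map must be a named list", "targetmr_param_error")

  exclusions <- list()
  drops <- list()
  note_excl <- function(gene, outcome, snp, reason) {
    exclusions[[length(exclusions) + 1L]] <<- data.frame(
      gene = gene, outcome = outcome, snp = snp, reason = reason,
      stringsAsFactors = FALSE)
  }
  note_drop <- function(snp, gene, outcome, reason) {
    drops[[length(drops) + 1L]] <<- data.frame(
      snp_id = snp, gene = gene, outcome = outcome, reason = reason,
      stringsAsFactors = FALSE)
  }

  no_target <- vapply(targets$genes, length, integer(1)) == 0
  for (s in targets$substance[no_target])
    note_excl(NA_character_, NA_character_, NA_character_,
              paste0("no_target_gene:", s))

  genes <- sort(unique(unlist(targets$genes)))
  exp_idx <- stats::setNames(seq_len(nrow(exposure_gwas)),
                             exposure_gwas$snp_id)
  out_idx <- lapply(outcome_gwas_map, function(df)
    stats::setNames(seq_len(nrow(df)), df$snp_id))

  # --- instrument selection ------------------------------------------------
  selected <- list()   # per gene: instrument eQTL rows
  m1 <- 0L             # total candidate instrument variants tested
  for (g in genes) {
    locus <- loci[loci$gene == g, , drop = FALSE]
    if (nrow(locus) == 0) {
      note_excl(g, NA_character_, NA_character_, "no_locus")
      next
    }
    recs <- eqtl[eqtl$gene == g, , drop = FALSE]
    pool <- list()
    for (tis in unique(recs$tissue)) {
      f <- filter_cis(recs[recs$tissue == tis, , drop = FALSE],
                      locus[1, ], cfg)
      if (nrow(f)) pool[[tis]] <- ld_prune(f, ld, cfg)
    }
    pool <- if (length(pool)) do.call(rbind, pool) else NULL
    if (is.null(pool) || nrow(pool) == 0) {
      note_excl(g, NA_character_, NA_character_, "no_instrument")
      next
    }
    m1 <- m1 + length(unique(pool$snp_id))
    best <- best_across_tissues(pool)
    selected[[g]] <- if (instruments_per_gene == "1") best else
      pool[pool$tissue == best$tissue, , drop = FALSE]
  }

  if (m1 == 0)
    abort_tmr("no gene yielded an eligible instrument", "targetmr_no_instrument")
  thr1 <- bonferroni_threshold(cfg$alpha, m1)

  # --- step 1: expression -> biomarker ------------------------------------
  estimate_from_pairs <- function(pairs, binary) {
    res <- if (nrow(pairs) == 1) {
      wald_ratio(pairs$beta_exposure, pairs$se_exposure,
                 pairs$beta_outcome, pairs$se_outcome, se_method = se_method)
    } else {
      ivw(pairs)
    }
    finalize_estimate(res$beta, res$se, ci_level = ci_level, binary = binary)
  }

  step1 <- list()
  step1_pairs <- list()   # instrument SNPs carried forward, per gene
  for (g in names(selected)) {
    inst <- selected[[g]]
    pairs <- list()
    for (i in seq_len(nrow(inst))) {
      row <- inst[i, ]
      j <- exp_idx[row$snp_id]
      if (is.na(j)) {
        note_drop(row$snp_id, g, "exposure", "absent_from_exposure")
        next
      }
      h <- harmonize(row, exposure_gwas[j, ],
                     palindrome_eaf_margin = palindrome_eaf_margin)
      if (h$status == "ok") pairs[[length(pairs) + 1L]] <- h$pair
      else note_drop(row$snp_id, g, "exposure", h$reason)
    }
    if (length(pairs) == 0) {
      note_excl(g, NA_character_, NA_character_, "no_instrument")
      next
    }
    pairs <- do.call(rbind, pairs)
    est <- estimate_from_pairs(pairs, binary = FALSE)
    step1[[g]] <- cbind(data.frame(gene = g, outcome = "exposure_biomarker",
                                   snp = paste(pairs$snp_id, collapse = ";"),
                                   n_snps = nrow(pairs),
                                   stringsAsFactors = FALSE),
                        est)
    step1_pairs[[g]] <- pairs$snp_id
  }
  if (length(step1) == 0)
    abort_tmr("no gene produced a step-1 estimate", "targetmr_no_instrument")
  step1 <- do.call(rbind, step1[order(names(step1))])
  rownames(step1) <- NULL
  step1$significant <- step1$pvalue < thr1

  # --- step 2: biomarker -> outcomes ---------------------------------------
  passing <- step1$gene[step1$significant]
  step2 <- list()
  for (g in passing) {
    for (o in names(outcome_gwas_map)) {
      odf <- outcome_gwas_map[[o]]
      pairs <- list()
      for (s in step1_pairs[[g]]) {
        exp_row <- exposure_gwas[exp_idx[s], ]
        px <- find_proxy(s, odf$snp_id, ld, r2_min = proxy_r2_min)
        if (is.null(px)) {
          note_excl(g, o, s, "no_proxy")
          next
        }
        orow <- odf[out_idx[[o]][px$proxy_id], ]
        h <- if (px$proxy_id == s) {
          harmonize(exp_row, orow,
                    palindrome_eaf_margin = palindrome_eaf_margin)
        } else {
          harmonize_proxy(exp_row, orow, px$r2,
                          palindrome_eaf_margin = palindrome_eaf_margin)
        }
        if (h$status == "ok") pairs[[length(pairs) + 1L]] <- h$pair
        else note_drop(s, g, o, h$reason)
      }
      if (length(pairs) == 0) next  # exclusion already logged per SNP
      pairs <- do.call(rbind, pairs)
      est <- estimate_from_pairs(pairs, binary = o %in% binary_outcomes)
      step2[[paste(g, o, sep = "\r")]] <-
        cbind(data.frame(gene = g, outcome = o,
                         snp = paste(pairs$snp_id, collapse = ";"),
                         n_snps = nrow(pairs),
                         proxy_used = any(pairs$proxy_used),
                         stringsAsFactors = FALSE),
              est)
    }
  }
  if (length(step2)) {
    step2 <- do.call(rbind, step2[order(names(step2))])
    rownames(step2) <- NULL
    m2 <- nrow(step2)
    thr2 <- bonferroni_threshold(cfg$alpha, m2)
    step2$significant <- step2$pvalue < thr2
  } else {
    step2 <- NULL
    m2 <- 0L
    thr2 <- NA_real_
  }

  structure(list(
    step1 = step1, step2 = step2,
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(gene = character(), outcome = character(),
                 snp = character(), reason = character()),
    drops = if (length(drops)) do.call(rbind, drops) else
      data.frame(snp_id = character(), gene = character(),
                 outcome = character(), reason = character()),
    m1 = m1, m2 = m2, threshold1 = thr1, threshold2 = thr2,
    config = cfg
  ), class = "two_step_result")
}

#' Flatten a two-step result into the standard results table
#'
#' @param x A `two_step_result`.
#' @param ... Unused.
#' @return A `data.frame` with columns `step, gene, outcome, snp, beta,
#'   ci_lower, ci_upper, or_, or_ci_lower, or_ci_upper, pvalue, n_snps,
#'   significant`.
#' @export
as.data.frame.two_step_result <- function(x, ...) {
  flat <- function(df, step) {
    data.frame(step = step, gene = df$gene, outcome = df$outcome,
               snp = df$snp, beta = df$beta,
               ci_lower = df$ci_lower, ci_upper = df$ci_upper,
               or_ = df$odds_ratio, or_ci_lower = df$or_ci_lower,
               or_ci_upper = df$or_ci_upper, pvalue = df$pvalue,
               n_snps = df$n_snps, significant = df$significant,
               stringsAsFactors = FALSE)
  }
  out <- flat(x$step1, 1L)
  if (!is.null(x$step2)) out <- rbind(out, flat(x$step2, 2L))
  rownames(out) <- NULL
  out
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf("Two-step MR result: %d gene(s) in step 1 (m1 = %d, gate p < %.3g)\n",
              nrow(x$step1), x$m1, x$threshold1))
  cat(sprintf("  step-1 significant genes: %d\n", sum(x$step1$significant)))
  if (!is.null(x$step2)) {
    cat(sprintf("  step-2 tests: %d (gate p < %.3g), significant: %d\n",
                x$m2, x$threshold2, sum(x$step2$significant)))
  } else {
    cat("  step 2 not run (no gene passed the step-1 gate)\n")
  }
  cat(sprintf("  exclusions: %d, harmonization drops: %d\n",
              nrow(x$exclusions), nrow(x$drops)))
  invisible(x)
}
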