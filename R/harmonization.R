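# Allele harmonization between exposure and outcome summary statistics,
# palindromic-SNP resolution by allele frequency, and LD-proxy lookup for
# instruments absent from the outcome panel.
#
# Drop reasons are machine-readable codes: "ambiguous_palindrome",
# "incompatible_alleles", "no_proxy".

BASE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' @keywords internal
is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & BASE_COMPLEMENT[ea] == oa
}

#' @keywords internal
hpair <- function(snp_id, exp, beta_outcome, se_outcome, eaf_outcome,
                  proxy_used = FALSE, proxy_r2 = NA_real_) {
  list(status = "ok", reason = NA_character_,
       pair = data.frame(snp_id = snp_id,
                         beta_exposure = exp$beta, se_exposure = exp$se,
                         eaf_exposure = exp$eaf,
                         beta_outcome = beta_outcome,
                         se_outcome = se_outcome,
                         eaf_outcome = eaf_outcome,
                         proxy_used = proxy_used, proxy_r2 = proxy_r2,
                         stringsAsFactors = FALSE))
}

#' @keywords internal
hdrop <- function(snp_id, reason) {
  list(status = "dropped", reason = reason, pair = NULL)
}

#' Harmonize one exposure/outcome record pair onto a common effect allele
#'
#' Aligns the outcome record's effect to the exposure record's effect
#' allele:
#' * identical alleles — pass through;
#' * swapped alleles — negate the outcome beta and complement its `eaf`;
#' * reverse-complement (strand-flipped) alleles — complement, then apply
#'   the identical/swapped rule;
#' * palindromic (A/T or C/G) SNPs — labels carry no strand information, so
#'   orientation is inferred from allele frequency: usable only when both
#'   `eaf`s lie outside `[0.5 - margin, 0.5 + margin]`; after label
#'   alignment, discordant frequency sides imply a strand flip (additional
#'   sign flip); otherwise the pair is dropped as `ambiguous_palindrome`;
#' * any other allele configuration — dropped as `incompatible_alleles`.
#'
#' Harmonization is an involution: harmonizing an already-aligned pair is
#' the identity.
#'
#' @param exp,out One-row summary-statistics records (exposure, outcome)
#'   for the same `snp_id`.
#' @param palindrome_eaf_margin Half-width of the frequency window around
#'   0.5 inside which a palindromic SNP is considered unresolvable
#'   (default 0.08, i.e. drop when both eafs are in 0.42–0.58).
#' @return A list with `status` (`"ok"` or `"dropped"`), `reason` (a drop
#'   code or `NA`), and `pair` (a one-row `data.frame` with
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `eaf_outcome`, `proxy_used`, `proxy_r2`).
#' @export
harmonize <- function(exp, out, palindrome_eaf_margin = 0.08) {
  if (exp$snp_id != out$snp_id)
    abort_tmr("harmonize: records are for different SNPs",
              "targetmr_param_error")
  e_ea <- exp$effect_allele; e_oa <- exp$other_allele
  o_ea <- out$effect_allele; o_oa <- out$other_allele
  beta_o <- out$beta; eaf_o <- out$eaf

  if (is_palindromic(e_ea, e_oa)) {
    # outcome alleles must be the same palindromic pair (possibly swapped)
    if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa)))
      return(hdrop(exp$snp_id, "incompatible_alleles"))
    if (is.na(exp$eaf) || is.na(eaf_o))
      return(hdrop(exp$snp_id, "ambiguous_palindrome"))
    lo <- 0.5 - palindrome_eaf_margin; hi <- 0.5 + palindrome_eaf_margin
    # align labels first
    if (o_ea == e_oa) {
      beta_o <- -beta_o
      eaf_o <- 1 - eaf_o
    }
    if ((exp$eaf > lo && exp$eaf < hi) || (eaf_o > lo && eaf_o < hi))
      return(hdrop(exp$snp_id, "ambiguous_palindrome"))
    if ((exp$eaf < 0.5) != (eaf_o < 0.5)) {
      # frequencies disagree after label alignment: strand flip
      beta_o <- -beta_o
      eaf_o <- 1 - eaf_o
    }
    return(hpair(exp$snp_id, exp, beta_o, out$se, eaf_o))
  }

  if (o_ea == e_ea && o_oa == e_oa) {
    # identical
  } else if (o_ea == e_oa && o_oa == e_ea) {
    beta_o <- -beta_o
    eaf_o <- if (is.na(eaf_o)) NA_real_ else 1 - eaf_o
  } else {
    c_ea <- unname(BASE_COMPLEMENT[o_ea])
    c_oa <- unname(BASE_COMPLEMENT[o_oa])
    if (identical(c_ea, e_ea) && identical(c_oa, e_oa)) {
      # strand flip only
    } else if (identical(c_ea, e_oa) && identical(c_oa, e_ea)) {
      beta_o <- -beta_o
      eaf_o <- if (is.na(eaf_o)) NA_real_ else 1 - eaf_o
    } else {
      return(hdrop(exp$snp_id, "incompatible_alleles"))
    }
  }
  hpair(exp$snp_id, exp, beta_o, out$se, eaf_o)
}

#' Find an LD proxy for an instrument absent from the outcome panel
#'
#' If `snp_id` is itself in `outcome_panel`, returns it with `r2 = 1`.
#' Otherwise returns the panel SNP with the largest `r2 >= r2_min` against
#' the query (ties broken by lexicographically smaller id), or `NULL` when
#' none qualifies — in which case the caller must exclude the gene-outcome
#' pair.
#'
#' @param snp_id Query instrument SNP.
#' @param outcome_panel Character vector of SNP ids present in the outcome
#'   GWAS.
#' @param ld An [ld_table()].
#' @param r2_min Minimum r-squared for a usable proxy (default 0.8,
#'   inclusive).
#' @return `list(proxy_id =, r2 =)` or `NULL`.
#' @export
find_proxy <- function(snp_id, outcome_panel, ld, r2_min = 0.8) {
  if (snp_id %in% outcome_panel)
    return(list(proxy_id = snp_id, r2 = 1.0))
  cand <- ld_partners(ld, snp_id, r2_min = r2_min)
  cand <- cand[cand$snp_id %in% outcome_panel, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand$r2, cand$snp_id), , drop = FALSE]
  list(proxy_id = cand$snp_id[1], r2 = cand$r2[1])
}

# Pair an instrument's exposure statistics with a *different* SNP's
# outcome record. Only r^2 (unsigned LD) is available, so the proxy's
# orientation relative to the instrument is inferred from allele
# frequency: high-LD pairs have nearly equal frequencies, and the proxy
# allele whose frequency matches the instrument's effect-allele frequency
# is taken as concordant. Unusable when either frequency is inside the
# palindrome window or missing (treated as no proxy).
#' @keywords internal
harmonize_proxy <- function(exp, proxy_out, proxy_r2,
                            palindrome_eaf_margin = 0.08) {
  if (is.na(exp$eaf) || is.na(proxy_out$eaf))
    return(hdrop(exp$snp_id, "no_proxy"))
  lo <- 0.5 - palindrome_eaf_margin; hi <- 0.5 + palindrome_eaf_margin
  if ((exp$eaf > lo && exp$eaf < hi) ||
      (proxy_out$eaf > lo && proxy_out$eaf < hi))
    return(hdrop(exp$snp_id, "no_proxy"))
  beta_o <- proxy_out$beta
  eaf_o <- proxy_out$eaf
  if ((exp$eaf < 0.5) != (eaf_o < 0.5)) {
    beta_o <- -beta_o
    eaf_o <- 1 - eaf_o
  }
  hpair(proxy_out$snp_id, exp, beta_o, proxy_out$se, eaf_o,
        proxy_used = TRUE, proxy_r2 = proxy_r2)
}
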