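# Gene-set enrichment against a ranked drug-perturbation profile: the
# weighted Kolmogorov-Smirnov running-sum enrichment score, a gene-label
# permutation null, and Benjamini-Hochberg adjustment across sets.

#' Construct a ranked profile
#'
#' Orders (gene, score) pairs by score descending, ties broken by
#' lexicographically smaller gene so that the ranking is total and
#' reproducible. Genes must be unique.
#'
#' @param genes Character vector of gene symbols.
#' @param scores Numeric ranking metric (e.g. a perturbation z-score).
#' @return A `data.frame` of class `ranked_profile` with columns `gene`,
#'   `score`, sorted.
#' @export
ranked_profile <- function(genes, scores) {
  if (length(genes) != length(scores))
    abort_tmr("ranked_profile: genes and scores differ in length",
              "targetmr_param_error")
  if (anyDuplicated(genes))
    abort_tmr("ranked_profile: duplicate gene symbols",
              "targetmr_param_error")
  ord <- order(-scores, genes)
  structure(data.frame(gene = as.character(genes)[ord],
                       score = as.numeric(scores)[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_profile", "data.frame"))
}

#' Assemble a disease gene set from several source lists
#'
#' Case-normalized (upper-case, whitespace-trimmed) union across the input
#' lists; the number of duplicates removed is recorded in the
#' `n_duplicates` attribute and reported via `message()`.
#'
#' @param lists A list of character vectors of gene symbols.
#' @param name Set name.
#' @return A list of class `gene_set` with elements `name` and `genes`
#'   (sorted unique symbols).
#' @export
assemble_gene_set <- function(lists, name = "gene_set") {
  all_genes <- toupper(trimws(unlist(lists, use.names = FALSE)))
  all_genes <- all_genes[nzchar(all_genes)]
  genes <- sort(unique(all_genes))
  n_dup <- length(all_genes) - length(genes)
  if (n_dup > 0)
    message(sprintf("assemble_gene_set: removed %d duplicate entr%s",
                    n_dup, if (n_dup == 1) "y" else "ies"))
  structure(list(name = name, genes = genes, n_duplicates = n_dup),
            class = "gene_set")
}

#' @keywords internal
set_genes <- function(set) {
  if (inherits(set, "gene_set")) set$genes else as.character(set)
}

# Signed maximum deviation from zero of the running sum, given the hit
# indicator and hit weights. The sign on an (effectively) exact tie
# between the positive and negative extremes is resolved toward the
# positive extreme, with a small relative tolerance so that the choice is
# stable under floating-point accumulation order.
#' @keywords internal
es_from_hits <- function(hit, w) {
  n <- length(hit)
  n_hit <- sum(hit)
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / n_hit, n)
  miss_dec <- if (n_hit < n) 1 / (n - n_hit) else 0
  running <- cumsum(ifelse(hit, inc, -miss_dec))
  max_pos <- max(running)
  min_neg <- min(running)
  tol <- 1e-9 * max(abs(max_pos), abs(min_neg), 1)
  if (max_pos + min_neg >= -tol) max_pos else min_neg
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked profile, genes in the set ("hits") increment the
#' running sum by `|score|^weight_p / sum_hits |score|^weight_p` and misses
#' decrement it by `1 / (N - N_hits)`. The enrichment score is the running
#' sum's maximum deviation from zero (signed; a tie between the positive
#' and negative extremes resolves to the positive one); it lies in
#' \[-1, 1\]. A set with no overlap with the profile is not testable and
#' raises a `targetmr_not_testable` condition.
#'
#' @param profile A [ranked_profile()] (or a `data.frame` with `gene`,
#'   `score`, already sorted by score descending).
#' @param set A [gene_set()][assemble_gene_set] or character vector.
#' @param weight_p Hit-weight exponent (default 1, the classic weighted
#'   statistic; 0 gives the unweighted Kolmogorov-Smirnov form).
#' @return The enrichment score.
#' @export
enrichment_score <- function(profile, set, weight_p = 1) {
  genes <- set_genes(set)
  hit <- profile$gene %in% genes
  n <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == 0)
    abort_tmr("enrichment_score: gene set has no overlap with the profile (not testable)",
              "targetmr_not_testable")
  w <- abs(profile$score)^weight_p
  es_from_hits(hit, w)
}

#' Gene-label permutation p-value for an enrichment score
#'
#' Recomputes the enrichment score on `B` random gene sets of the same
#' overlap size drawn from the profile's genes, and returns
#' `p = (1 + #{|ES_perm| >= |ES_obs|}) / (B + 1)`. Deterministic given
#' `seed`.
#'
#' @inheritParams enrichment_score
#' @param B Number of permutations (>= 1, default 1000).
#' @param seed Integer seed.
#' @return The permutation p-value, in `[1 / (B + 1), 1]`.
#' @export
permutation_pvalue <- function(profile, set, B = 1000, seed = 1,
                               weight_p = 1) {
  if (B < 1)
    abort_tmr("permutation_pvalue: B must be >= 1", "targetmr_param_error")
  es_obs <- enrichment_score(profile, set, weight_p = weight_p)
  k <- sum(profile$gene %in% set_genes(set))
  n <- nrow(profile)
  w <- abs(profile$score)^weight_p
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(B)) {
    hit <- logical(n)
    hit[sample.int(n, k)] <- TRUE
    if (abs(es_from_hits(hit, w)) >= abs(es_obs)) n_ge <- n_ge + 1L
  }
  (1 + n_ge) / (B + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (via `stats::p.adjust(method = "BH")`) after
#' validating that every input lies in (0, 1]; input order is preserved.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the input, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1))
    abort_tmr("bh_adjust: p-values must be in (0, 1]",
              "targetmr_param_error")
  stats::p.adjust(pvalues, method = "BH")
}

#' Score several gene sets against one ranked profile
#'
#' Computes the enrichment score and permutation p-value for each set, then
#' BH-adjusts across the testable sets. Sets with no overlap are returned
#' with `testable = FALSE` and `NA` statistics.
#'
#' @inheritParams permutation_pvalue
#' @param sets A named list of gene sets (character vectors or `gene_set`
#'   objects).
#' @return A `data.frame` with columns `set`, `es`, `p_perm`, `p_adjust`,
#'   `n_overlap`, `testable`.
#' @export
run_gsea <- function(profile, sets, B = 1000, seed = 1, weight_p = 1) {
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, function(s)
      if (inherits(s, "gene_set")) s$name else "set", "")
  rows <- lapply(seq_along(sets), function(i) {
    genes <- set_genes(sets[[i]])
    k <- sum(profile$gene %in% genes)
    if (k == 0) {
      return(data.frame(set = names(sets)[i], es = NA_real_,
                        p_perm = NA_real_, p_adjust = NA_real_,
                        n_overlap = 0L, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    es <- enrichment_score(profile, genes, weight_p = weight_p)
    p <- permutation_pvalue(profile, genes, B = B, seed = seed + i,
                            weight_p = weight_p)
    data.frame(set = names(sets)[i], es = es, p_perm = p,
               p_adjust = NA_real_, n_overlap = k, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$testable))
    out$p_adjust[out$testable] <- bh_adjust(out$p_perm[out$testable])
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name, description, gene, gene, ...`.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    abort_tmr(sprintf("input file not found: %s", path), "targetmr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      abort_tmr("malformed GMT line (need name, description, >= 1 gene)",
                "targetmr_schema_error")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (or `gene_set` objects).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    genes <- set_genes(sets[[i]])
    paste(c(names(sets)[i], "na", genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
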