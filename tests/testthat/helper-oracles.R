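# Independent reference implementations used as oracles. These are kept
# deliberately naive (matrix-based, explicit loops) and share no code with
# the package internals they check.

# Greedy pruning on an explicit r^2 matrix: repeatedly keep the index with
# the smallest p (ties: smaller id), discard all remaining indices with
# r2 >= thr against it.
oracle_greedy_prune <- function(ids, pvals, r2mat, thr) {
  stopifnot(nrow(r2mat) == length(ids))
  alive <- seq_along(ids)
  kept <- integer(0)
  while (length(alive)) {
    o <- order(pvals[alive], ids[alive])
    head_i <- alive[o[1]]
    kept <- c(kept, head_i)
    alive <- setdiff(alive, head_i)
    alive <- alive[r2mat[alive, head_i] < thr]
  }
  kept
}

# Running-sum enrichment score by explicit walk. The signed extremum rule
# (positive extreme wins a tie, small relative tolerance) matches the
# documented statistic definition.
oracle_runsum <- function(genes_ranked, scores_ranked, set, p) {
  n <- length(genes_ranked)
  hit <- genes_ranked %in% set
  nh <- sum(hit)
  stopifnot(nh >= 1)
  w <- abs(scores_ranked)^p
  denom <- sum(w[hit])
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      acc <- acc + (if (denom > 0) w[i] / denom else 1 / nh)
    } else {
      acc <- acc - 1 / (n - nh)
    }
    run[i] <- acc
  }
  run
}

oracle_es <- function(genes_ranked, scores_ranked, set, p) {
  run <- oracle_runsum(genes_ranked, scores_ranked, set, p)
  max_pos <- max(run)
  min_neg <- min(run)
  tol <- 1e-9 * max(abs(max_pos), abs(min_neg), 1)
  if (max_pos + min_neg >= -tol) max_pos else min_neg
}

# TRUE when the positive and negative running-sum extremes tie in
# magnitude (the ES sign is then fixed by convention, not by the data).
oracle_es_tied <- function(genes_ranked, scores_ranked, set, p) {
  run <- oracle_runsum(genes_ranked, scores_ranked, set, p)
  isTRUE(all.equal(max(run), -min(run)))
}

# Fixed-effect weighted least squares through the origin, by matrix
# algebra: beta = (X'WX)^{-1} X'W y, se = sqrt((X'WX)^{-1}).
oracle_wls_origin <- function(bx, by, sey) {
  X <- matrix(bx, ncol = 1)
  W <- diag(1 / sey^2, nrow = length(sey))
  xtwx <- t(X) %*% W %*% X
  beta <- solve(xtwx, t(X) %*% W %*% matrix(by, ncol = 1))
  list(beta = as.numeric(beta), se = sqrt(as.numeric(solve(xtwx))))
}

# Quick builders for summary-statistics records.
make_record <- function(snp_id = "rs1", chrom = "1", pos = 1000000,
                        ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                        se = 0.02, pvalue = NULL, n = 10000,
                        gene = NULL, tissue = NULL) {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = se, pvalue = pvalue, n = n,
                   stringsAsFactors = FALSE)
  if (!is.null(gene)) {
    df$gene <- gene
    df$tissue <- if (is.null(tissue)) "t1" else tissue
  }
  df
}

make_records <- function(...) do.call(rbind, list(...))

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
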