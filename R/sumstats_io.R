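# Readers/writers for every table the pipeline touches: GWAS and eQTL
# summary statistics, pairwise LD, the drug -> target-gene table, gene loci
# and MR result tables. All files are tab-delimited with a header row;
# genomic coordinates are 1-based inclusive throughout.

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")
EQTL_COLS <- c(SUMSTATS_COLS, "gene", "tissue")
RESULT_COLS <- c("step", "gene", "outcome", "snp", "beta", "ci_lower",
                 "ci_upper", "or_", "or_ci_lower", "or_ci_upper", "pvalue",
                 "n_snps", "significant")

VALID_BASES <- c("A", "C", "G", "T")

#' Read GWAS or eQTL summary statistics
#'
#' Reads a tab-delimited summary-statistics file and validates every row
#' against the schema invariants: single-nucleotide alleles with effect
#' allele distinct from the other allele, `se > 0`, `pvalue` in (0, 1],
#' `eaf` in (0, 1), `n > 0`. Row order is preserved.
#'
#' A missing `eaf` (empty or `NA`) is tolerated for `kind = "gwas"` — some
#' outcome GWAS releases carry no frequency column — but such records cannot
#' be used to orient palindromic SNPs downstream (see [harmonize()]).
#' Duplicate `snp_id` within one GWAS file, or within one (gene, tissue)
#' stratum of an eQTL file, is an error.
#'
#' @param path Path to a tab-delimited file with a header row. Required
#'   columns: `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`, plus `gene` and `tissue` when
#'   `kind = "eqtl"`.
#' @param kind `"gwas"` or `"eqtl"`.
#' @return A `data.frame`, one validated row per variant, in file order.
#' @export
read_sumstats <- function(path, kind = c("gwas", "eqtl")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path)
  req <- if (kind == "eqtl") EQTL_COLS else SUMSTATS_COLS
  check_columns(df, req, path)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- parse_num(df[[col]])
  }
  for (col in c("snp_id", "chrom", "effect_allele", "other_allele")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (kind == "eqtl") {
    df$gene <- as.character(df$gene)
    df$tissue <- as.character(df$tissue)
  }
  validate_sumstats(df, kind = kind, allow_missing_eaf = (kind == "gwas"))
  df[, req]
}

# Row-level invariant checks; errors cite the 1-based file line
# (header is line 1, so data row i is line i + 1).
#' @keywords internal
validate_sumstats <- function(df, kind, allow_missing_eaf = FALSE) {
  line <- seq_len(nrow(df)) + 1L
  fail <- function(rows, what) {
    abort_tmr(sprintf("invalid summary-statistics row (%s) at line %s",
                      what, paste(line[rows][1], collapse = ", ")),
              "targetmr_invalid_record")
  }
  bad <- !(df$effect_allele %in% VALID_BASES) |
    !(df$other_allele %in% VALID_BASES)
  if (any(bad)) fail(bad, "allele not a single base in {A,C,G,T}")
  bad <- df$effect_allele == df$other_allele
  if (any(bad)) fail(bad, "effect_allele equals other_allele")
  bad <- is.na(df$se) | df$se <= 0
  if (any(bad)) fail(bad, "se must be > 0")
  bad <- is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  if (any(bad)) fail(bad, "pvalue must be in (0, 1]")
  if (allow_missing_eaf) {
    bad <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  } else {
    bad <- is.na(df$eaf) | df$eaf <= 0 | df$eaf >= 1
  }
  if (any(bad)) fail(bad, "eaf must be in (0, 1)")
  bad <- is.na(df$n) | df$n <= 0
  if (any(bad)) fail(bad, "n must be > 0")
  bad <- is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos)
  if (any(bad)) fail(bad, "pos must be a positive integer")
  if (kind == "eqtl") {
    bad <- is.na(df$gene) | !nzchar(df$gene)
    if (any(bad)) fail(bad, "gene must be non-empty")
    key <- paste(df$gene, df$tissue, df$snp_id, sep = "\r")
  } else {
    key <- df$snp_id
  }
  dup <- duplicated(key)
  if (any(dup)) fail(dup, "duplicate snp_id")
  invisible(df)
}

#' Write summary statistics
#'
#' Inverse of [read_sumstats()]: floats are written in ASCII with enough
#' precision (15 significant digits) that a write/read round trip is exact
#' to at least 12 significant digits.
#'
#' @param df A summary-statistics `data.frame` (GWAS or eQTL schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  out <- df
  for (col in intersect(c("eaf", "beta", "se", "pvalue"), names(out))) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the drug-target table
#'
#' Parses a tab-delimited table of lipid-lowering drug classes, substances,
#' DrugBank identifiers and semicolon-separated target gene symbols
#' (`"PPARA; PPARD; PPARG"` style). Gene symbols are whitespace-trimmed; an
#' empty cell yields an empty gene list (some substances, e.g. Acipimox,
#' have no annotated protein target).
#'
#' @param path Tab-delimited file with columns `drug_class`, `substance`,
#'   `drugbank_id`, `genes`.
#' @return A `data.frame` with a list-column `genes`.
#' @export
read_target_table <- function(path) {
  df <- read_tsv_checked(path)
  check_columns(df, c("drug_class", "substance", "drugbank_id", "genes"), path)
  df$drugbank_id <- as.character(df$drugbank_id)
  bad <- !grepl("^DB[0-9]{5}$", df$drugbank_id)
  if (any(bad)) {
    abort_tmr(sprintf("malformed DrugBank ID '%s' at line %d",
                      df$drugbank_id[bad][1], which(bad)[1] + 1L),
              "targetmr_invalid_record")
  }
  if (anyDuplicated(df$substance)) {
    abort_tmr("duplicate substance in drug-target table",
              "targetmr_invalid_record")
  }
  genes <- lapply(as.character(df$genes), function(g) {
    if (is.na(g) || !nzchar(trimws(g))) return(character(0))
    trimws(strsplit(g, ";", fixed = TRUE)[[1]])
  })
  data.frame(drug_class = as.character(df$drug_class),
             substance = as.character(df$substance),
             drugbank_id = df$drugbank_id,
             genes = I(genes),
             stringsAsFactors = FALSE)
}

#' Read gene loci
#'
#' @param path Tab-delimited file with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive coordinates, `start <= end`).
#' @return A `data.frame` of loci.
#' @export
read_gene_loci <- function(path) {
  df <- read_tsv_checked(path)
  check_columns(df, c("gene", "chrom", "start", "end"), path)
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$start <- parse_num(df$start)
  df$end <- parse_num(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start > df$end
  if (any(bad)) {
    abort_tmr(sprintf("invalid locus (start > end) at line %d",
                      which(bad)[1] + 1L), "targetmr_invalid_record")
  }
  df[, c("gene", "chrom", "start", "end")]
}

#' Write MR result rows
#'
#' Writes a results table with exactly the columns `step, gene, outcome,
#' snp, beta, ci_lower, ci_upper, or_, or_ci_lower, or_ci_upper, pvalue,
#' n_snps, significant`. Accepts either a [run_two_step()] result object or
#' a pre-assembled `data.frame` with those columns.
#'
#' @param estimates A `two_step_result` object or a results `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  df <- if (inherits(estimates, "two_step_result")) {
    as.data.frame(estimates)
  } else {
    estimates
  }
  check_columns(df, RESULT_COLS, "results table")
  out <- df[, RESULT_COLS]
  for (col in c("beta", "ci_lower", "ci_upper", "or_", "or_ci_lower",
                "or_ci_upper", "pvalue")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read MR result rows written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return A `data.frame` with the standard result columns.
#' @export
read_results <- function(path) {
  df <- read_tsv_checked(path)
  check_columns(df, RESULT_COLS, path)
  for (col in c("beta", "ci_lower", "ci_upper", "or_", "or_ci_lower",
                "or_ci_upper", "pvalue")) {
    df[[col]] <- parse_num(df[[col]])
  }
  df$step <- as.integer(df$step)
  df$n_snps <- as.integer(df$n_snps)
  df$significant <- as.logical(df$significant)
  df[, RESULT_COLS]
}

#' @keywords internal
read_tsv_checked <- function(path) {
  if (!file.exists(path)) {
    abort_tmr(sprintf("input file not found: %s", path), "targetmr_io_error")
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' @keywords internal
check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort_tmr(sprintf("%s: missing required column(s): %s",
                      what, paste(miss, collapse = ", ")),
              "targetmr_schema_error")
  }
  invisible(df)
}
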