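# Pairwise r^2 lookup table. Symmetric on query; r2(a, a) = 1 implicitly;
# an absent pair means r^2 = 0 by convention. Backed by a hashed
# environment so pruning over many SNPs stays O(pairs).

#' Construct an LD table
#'
#' @param entries A `data.frame` with columns `snp_a`, `snp_b`, `r2`
#'   (`r2` in \[0, 1\]). Self pairs are ignored (implicitly 1).
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(entries = data.frame(snp_a = character(),
                                          snp_b = character(),
                                          r2 = numeric())) {
  check_columns(entries, c("snp_a", "snp_b", "r2"), "LD table")
  entries$snp_a <- as.character(entries$snp_a)
  entries$snp_b <- as.character(entries$snp_b)
  entries$r2 <- parse_num(entries$r2)
  bad <- is.na(entries$r2) | entries$r2 < 0 | entries$r2 > 1
  if (any(bad)) {
    abort_tmr(sprintf("LD r2 outside [0, 1] at row %d", which(bad)[1]),
              "targetmr_invalid_record")
  }
  entries <- entries[entries$snp_a != entries$snp_b, , drop = FALSE]
  idx <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  if (nrow(entries)) {
    keys <- ld_key(entries$snp_a, entries$snp_b)
    for (i in seq_len(nrow(entries))) assign(keys[i], entries$r2[i], envir = idx)
  }
  structure(list(entries = entries, index = idx), class = "ld_table")
}

#' @keywords internal
ld_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Query pairwise r-squared
#'
#' Symmetric lookup: `ld_r2(ld, a, b)` equals `ld_r2(ld, b, a)`;
#' `ld_r2(ld, a, a)` is 1; an absent pair returns 0.
#'
#' @param ld An [ld_table()].
#' @param a,b SNP identifiers (vectorised over equal lengths).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  a <- as.character(a); b <- as.character(b)
  keys <- ld_key(a, b)
  out <- vapply(keys, function(k) {
    v <- get0(k, envir = ld$index, ifnotfound = 0)
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  out[a == b] <- 1
  out
}

#' SNPs linked to a query SNP above an r-squared floor
#'
#' @param ld An [ld_table()].
#' @param snp_id Query SNP.
#' @param r2_min Minimum r-squared (inclusive).
#' @return `data.frame` with columns `snp_id`, `r2`, the partners of
#'   `snp_id` with `r2 >= r2_min` (the query SNP itself is not returned).
#' @export
ld_partners <- function(ld, snp_id, r2_min = 0) {
  stopifnot(inherits(ld, "ld_table"))
  e <- ld$entries
  hit <- (e$snp_a == snp_id | e$snp_b == snp_id) & e$r2 >= r2_min
  partner <- ifelse(e$snp_a[hit] == snp_id, e$snp_b[hit], e$snp_a[hit])
  data.frame(snp_id = partner, r2 = e$r2[hit], stringsAsFactors = FALSE)
}

#' Read an LD table from a long-format TSV
#'
#' @param path Tab-delimited file with columns `snp_a`, `snp_b`, `r2`.
#' @return An [ld_table()].
#' @export
read_ld <- function(path) {
  ld_table(read_tsv_checked(path))
}

#' Write an LD table to a long-format TSV
#'
#' @param ld An [ld_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  out <- ld$entries
  out$r2 <- fmt_num(out$r2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
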