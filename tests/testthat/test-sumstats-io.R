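# Strict-schema readers/writers for summary statistics, LD, targets, loci
# and results.

test_that("well-formed GWAS files round-trip in file order", {
  df <- make_records(
    make_record("rs1", beta = 0.123456789012345, se = 0.01),
    make_record("rs2", beta = -0.2, se = 0.02, ea = "C", oa = "T"),
    make_record("rs3", beta = 1e-4, se = 0.5, eaf = 0.011)
  )
  path <- tempfile(fileext = ".tsv")
  write_sumstats(df, path)
  back <- read_sumstats(path, kind = "gwas")
  expect_identical(back$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(back$beta, df$beta, tolerance = 1e-12)
  expect_equal(back$se, df$se, tolerance = 1e-12)
  expect_identical(back$effect_allele, df$effect_allele)
})

test_that("row-level invariant violations cite the offending line", {
  df <- make_records(
    make_record("rs1"), make_record("rs2"), make_record("rs3"),
    make_record("rs4"), make_record("rs5", se = 0)
  )
  df$pvalue[5] <- 0.5  # keep pvalue valid so only se triggers
  path <- write_tsv_fixture(df)
  err <- tryCatch(read_sumstats(path, "gwas"), error = identity)
  expect_s3_class(err, "targetmr_invalid_record")
  expect_match(conditionMessage(err), "line 6")
  expect_match(conditionMessage(err), "se")
})

test_that("schema errors name the missing column", {
  df <- make_record("rs1")
  df$se <- NULL
  path <- write_tsv_fixture(df)
  err <- tryCatch(read_sumstats(path, "gwas"), error = identity)
  expect_s3_class(err, "targetmr_schema_error")
  expect_match(conditionMessage(err), "se")
})

test_that("malformed rows always raise typed errors, never coerce", {
  base <- make_record("rs1")
  corruptions <- list(
    function(d) { d$effect_allele <- "AT"; d },
    function(d) { d$other_allele <- "N"; d },
    function(d) { d$other_allele <- d$effect_allele; d },
    function(d) { d$pvalue <- 0; d },
    function(d) { d$pvalue <- 1.5; d },
    function(d) { d$eaf <- 1.2; d },
    function(d) { d$n <- -5; d },
    function(d) { d$pos <- 0; d }
  )
  for (corrupt in corruptions) {
    path <- write_tsv_fixture(corrupt(base))
    expect_error(read_sumstats(path, "gwas"),
                 class = "targetmr_invalid_record")
  }
})

test_that("eQTL records keep per-tissue rows distinct; duplicates error", {
  df <- make_records(
    make_record("rs1", gene = "PPARG", tissue = "adipose"),
    make_record("rs1", gene = "PPARG", tissue = "muscle"),
    make_record("rs2", gene = "PPARG", tissue = "adipose"),
    make_record("rs2", gene = "PPARG", tissue = "muscle")
  )
  path <- write_tsv_fixture(df)
  back <- read_sumstats(path, "eqtl")
  expect_equal(nrow(back), 4)
  expect_equal(sort(table(back$tissue), decreasing = TRUE),
               sort(table(c("adipose", "adipose", "muscle", "muscle")),
                    decreasing = TRUE))

  dup <- rbind(df, df[1, ])
  expect_error(read_sumstats(write_tsv_fixture(dup), "eqtl"),
               class = "targetmr_invalid_record")
  # same snp in two tissues is fine; in one tissue twice is not
  expect_error(read_sumstats(write_tsv_fixture(rbind(df[1, ], df[1, ])), "eqtl"),
               class = "targetmr_invalid_record")
})

test_that("missing eaf tolerated for outcome GWAS but not for eQTL", {
  df <- make_record("rs1")
  df$eaf <- NA
  path <- write_tsv_fixture(df)
  back <- read_sumstats(path, "gwas")
  expect_true(is.na(back$eaf))
  df$gene <- "PPARG"; df$tissue <- "t1"
  expect_error(read_sumstats(write_tsv_fixture(df), "eqtl"),
               class = "targetmr_invalid_record")
})

test_that("unicode minus and scientific notation parse", {
  df <- make_record("rs1")
  df$beta <- "−0.25"
  df$pvalue <- "1.5E-8"
  path <- write_tsv_fixture(df)
  back <- read_sumstats(path, "gwas")
  expect_equal(back$beta, -0.25)
  expect_equal(back$pvalue, 1.5e-8)
})

test_that("packaged drug-target table parses per the published layout", {
  path <- system.file("extdata", "drug_targets.tsv", package = "targetmr")
  tt <- read_target_table(path)
  expect_equal(nrow(tt), 19)
  bz <- tt$genes[[which(tt$substance == "Bezafibrate")]]
  expect_length(bz, 7)
  expect_identical(bz[7], "RXRG")
  expect_identical(tt$drugbank_id[tt$substance == "Bezafibrate"], "DB01393")
  # substance with no annotated target gene: empty list, not an error
  expect_length(tt$genes[[which(tt$substance == "Acipimox")]], 0)
  expect_false(anyDuplicated(tt$drugbank_id) > 0)
})

test_that("malformed DrugBank identifiers are rejected", {
  df <- data.frame(drug_class = "x", substance = "y",
                   drugbank_id = "DB123", genes = "HMGCR")
  expect_error(read_target_table(write_tsv_fixture(df)),
               class = "targetmr_invalid_record")
})

test_that("gene symbols in the target table are whitespace-trimmed", {
  df <- data.frame(drug_class = "x", substance = "y",
                   drugbank_id = "DB00001", genes = "PPARA ;  PPARG")
  tt <- read_target_table(write_tsv_fixture(df))
  expect_identical(tt$genes[[1]], c("PPARA", "PPARG"))
})

test_that("LD lookup is symmetric, absent pairs are 0, self pairs are 1", {
  ld <- ld_table(data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5))
  expect_equal(ld_r2(ld, "s1", "s2"), 0.5)
  expect_equal(ld_r2(ld, "s2", "s1"), 0.5)
  expect_equal(ld_r2(ld, "s1", "s9"), 0)
  expect_equal(ld_r2(ld, "s9", "s9"), 1)
})

test_that("LD r2 outside [0, 1] is rejected; files round-trip", {
  expect_error(ld_table(data.frame(snp_a = "a", snp_b = "b", r2 = 1.2)),
               class = "targetmr_invalid_record")
  ld <- ld_table(data.frame(snp_a = c("a", "c"), snp_b = c("b", "d"),
                            r2 = c(0.25, 0.8)))
  path <- tempfile(fileext = ".tsv")
  write_ld(ld, path)
  back <- read_ld(path)
  expect_equal(ld_r2(back, "a", "b"), 0.25)
  expect_equal(ld_r2(back, "d", "c"), 0.8)
})

test_that("results tables round-trip field-by-field to 12 digits", {
  est <- data.frame(
    step = c(1L, 2L, 2L), gene = c("PPARG", "PPARG", "HMGCR"),
    outcome = c("LDL_C", "FN_BMD", "fracture"),
    snp = c("rs310749", "rs310749", "rs3846662"),
    beta = c(-0.183456789012345, -1.381, 0.138881),
    ci_lower = c(-0.259, -2.218, -0.092),
    ci_upper = c(-0.107, -0.544, 0.371),
    or_ = c(NA, NA, 1.149),
    or_ci_lower = c(NA, NA, 0.912),
    or_ci_upper = c(NA, NA, 1.449),
    pvalue = c(1.97e-06, 0.001219, 0.2397),
    n_snps = c(1L, 1L, 1L),
    significant = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  write_results(est, path)
  back <- read_results(path)
  for (col in c("beta", "ci_lower", "ci_upper", "or_", "pvalue")) {
    expect_equal(back[[col]], est[[col]], tolerance = 1e-12)
  }
  expect_identical(back$gene, est$gene)
  expect_identical(back$significant, est$significant)
})

test_that("gene loci validate coordinate order", {
  df <- data.frame(gene = "PPARG", chrom = "3", start = 12287368,
                   end = 12434356)
  loci <- read_gene_loci(write_tsv_fixture(df))
  expect_equal(loci$start, 12287368)
  df$end <- 1
  expect_error(read_gene_loci(write_tsv_fixture(df)),
               class = "targetmr_invalid_record")
})
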