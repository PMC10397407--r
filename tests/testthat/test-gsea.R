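# Gene-set assembly, running-sum enrichment score, permutation null,
# BH adjustment.

test_that("gene-set assembly is a case-normalized deduplicated union", {
  expect_message(s <- assemble_gene_set(list(c("A", "B"), c("B", "C"))),
                 "1 duplicate")
  expect_setequal(s$genes, c("A", "B", "C"))
  expect_equal(s$n_duplicates, 1)

  s2 <- assemble_gene_set(list(letters[1:2], letters[3:5], letters[6:9],
                               letters[10:14]))
  expect_length(s2$genes, 14)

  expect_message(s3 <- assemble_gene_set(list(c("Sost", "SOST", " sost "))),
                 "2 duplicate")
  expect_identical(s3$genes, "SOST")
})

test_that("extreme single-hit sets reach the ES bounds", {
  prof <- ranked_profile(sprintf("g%d", 1:5), c(5, 4, 3, 2, 1))
  expect_equal(enrichment_score(prof, "g1", weight_p = 0), 1.0)
  expect_equal(enrichment_score(prof, "g5", weight_p = 0), -1.0)
  # a set covering the whole profile walks straight up to 1
  expect_equal(enrichment_score(prof, prof$gene, weight_p = 0), 1.0)
})

test_that("profiles sort descending with lexicographic tie-breaks", {
  prof <- ranked_profile(c("b", "a", "c"), c(1, 2, 1))
  expect_identical(prof$gene, c("a", "b", "c"))
  expect_error(ranked_profile(c("a", "a"), c(1, 2)),
               class = "targetmr_param_error")
})

test_that("weighted ES matches the brute-force oracle on random cases", {
  set.seed(13)
  for (trial in 1:20) {
    n <- 20
    prof <- ranked_profile(sprintf("g%02d", 1:n), rnorm(n))
    set <- sample(prof$gene, 5)
    expect_equal(enrichment_score(prof, set, weight_p = 1),
                 oracle_es(prof$gene, prof$score, set, p = 1),
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with fgsea's statistic at weight 1", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  for (trial in 1:10) {
    n <- 30
    prof <- ranked_profile(sprintf("g%02d", 1:n), rnorm(n))
    idx <- sort(sample(n, 6))
    ours <- enrichment_score(prof, prof$gene[idx], weight_p = 1)
    ref <- fgsea::calcGseaStat(stats = stats::setNames(prof$score, prof$gene),
                               selectedStats = idx, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("ES is invariant to uniform positive rescaling at weight 1", {
  set.seed(15)
  prof <- ranked_profile(sprintf("g%02d", 1:25), rnorm(25))
  set <- sample(prof$gene, 6)
  es1 <- enrichment_score(prof, set, weight_p = 1)
  prof2 <- prof
  prof2$score <- prof2$score * 37.5
  expect_equal(enrichment_score(prof2, set, weight_p = 1), es1)
})

test_that("reversing the ranking flips the ES sign (unweighted)", {
  set.seed(16)
  for (trial in 1:10) {
    n <- 15
    sc <- sort(runif(n, -3, 3), decreasing = TRUE)
    prof <- ranked_profile(sprintf("g%02d", 1:n), sc)
    rev_prof <- ranked_profile(prof$gene, -sc)
    set <- sample(prof$gene, 4)
    es <- enrichment_score(prof, set, weight_p = 0)
    es_rev <- enrichment_score(rev_prof, set, weight_p = 0)
    expect_equal(abs(es_rev), abs(es), tolerance = 1e-12)
    if (!oracle_es_tied(prof$gene, prof$score, set, 0)) {
      # sign flips whenever the extremum is not a tie (tied extremes
      # resolve to the positive one by convention on both sides)
      expect_equal(es_rev, -es, tolerance = 1e-12)
    }
  }
})

test_that("zero-overlap sets are flagged not-testable", {
  prof <- ranked_profile(c("a", "b", "c"), 3:1)
  expect_error(enrichment_score(prof, c("x", "y")),
               class = "targetmr_not_testable")
  res <- run_gsea(prof, list(good = c("a", "b"), none = c("x")),
                  B = 50, seed = 1)
  expect_false(res$testable[res$set == "none"])
  expect_true(is.na(res$p_adjust[res$set == "none"]))
  expect_equal(res$n_overlap[res$set == "good"], 2)
})

test_that("permutation p-values hit the lower bound for planted sets", {
  set.seed(17)
  n <- 40
  prof <- ranked_profile(sprintf("g%02d", 1:n), sort(rnorm(n, 0, 2),
                                                     decreasing = TRUE))
  top <- prof$gene[1:8]
  p <- permutation_pvalue(prof, top, B = 1000, seed = 3)
  expect_equal(p, 1 / 1001)
  # determinism
  expect_identical(permutation_pvalue(prof, top, B = 200, seed = 9),
                   permutation_pvalue(prof, top, B = 200, seed = 9))
})

test_that("permutation p-values are roughly uniform for random sets", {
  set.seed(18)
  n <- 50
  prof <- ranked_profile(sprintf("g%02d", 1:n), rnorm(n))
  ps <- vapply(1:20, function(i) {
    set <- sample(prof$gene, 6)
    permutation_pvalue(prof, set, B = 1000, seed = 11 + i)
  }, 0)
  expect_gt(mean(ps), 0.2)
  expect_lte(max(ps), 1)
  expect_gt(min(ps), 1 / 1001 - 1e-12)
})

test_that("BH adjustment follows the step-up minima", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(19)
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone when sorted by raw p
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), class = "targetmr_param_error")
  expect_error(bh_adjust(c(0.5, 1.1)), class = "targetmr_param_error")
})

test_that("run_gsea flags planted enrichment after BH adjustment", {
  set.seed(21)
  n <- 60
  sc <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  prof <- ranked_profile(sprintf("g%02d", 1:n), sc)
  sets <- list(planted = prof$gene[1:10],
               random1 = sample(prof$gene, 10),
               random2 = sample(prof$gene, 10))
  res <- run_gsea(prof, sets, B = 500, seed = 2)
  expect_lt(res$p_adjust[res$set == "planted"], 0.05)
  expect_true(all(res$p_adjust >= res$p_perm, na.rm = TRUE))
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("D", "E"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, sets)
})
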