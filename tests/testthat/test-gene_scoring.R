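test_that("map_snps_to_genes honors the inclusive window and multi-gene SNPs", {
  genes <- data.frame(gene_id = c("A", "B"), chromosome = c(1L, 1L),
                      start = c(10000L, 18000L), end = c(20000L, 30000L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                     chromosome = 1L,
                     position = c(5000L, 4999L, 19000L, 25005L, 35001L),
                     p_value = rep(0.5, 5), stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, genes, window_bp = 5000)
  expect_equal(m$A, c("s1", "s3"))          # 5000 == start - window: inclusive
  expect_equal(m$B, c("s3", "s4"))          # s3 inside both overlapping genes
  expect_false("s2" %in% unlist(m))         # 4999 is one bp outside
  # gene with no SNPs is absent
  genes2 <- rbind(genes, data.frame(gene_id = "C", chromosome = 22L,
                                    start = 1L, end = 10L))
  expect_named(map_snps_to_genes(snps, genes2, 5000), c("A", "B"))
})

test_that("build_asm_gene_sets implements both membership routes", {
  mapping <- list(A = c("rs9", "rs2"), B = c("rs3"), C = c("rs4"))
  pairs <- data.frame(snp_id = c("rs9", "rs9"),
                      snp_chromosome = 1L, snp_position = 1L,
                      cpg_chromosome = c(1L, 2L), cpg_position = c(10L, 20L),
                      target_gene_id = c("A", "B"), mode = c("cis", "trans"),
                      p_value = 0.01, stringsAsFactors = FALSE)
  sets <- build_asm_gene_sets(mapping, pairs)
  expect_equal(sets$is_asm, c(TRUE, TRUE, FALSE))
  expect_equal(sets$asm_route, c("both", "cpg_target", "none"))
  # unknown target gene: warning, pair ignored
  pairs2 <- pairs
  pairs2$target_gene_id <- c("A", "NOPE")
  expect_warning(sets2 <- build_asm_gene_sets(mapping, pairs2), "absent")
  expect_equal(sets2$is_asm, c(TRUE, FALSE, FALSE))
})

test_that("gene_min_p follows the ASM rule with tie-breaking", {
  p <- c(a1 = 0.3, a2 = 0.02, x1 = 0.001, x2 = 0.7)
  pos <- c(a1 = 100, a2 = 200, x1 = 300, x2 = 400)
  # ASM SNPs only, the smaller non-ASM p is ignored
  r <- gene_min_p(c("a1", "a2", "x1"), c("a1", "a2"), p, pos)
  expect_equal(r$min_p, 0.02)
  expect_equal(r$representative_snp, "a2")
  # CpG-target-route gene without in-gene ASM SNPs: all SNPs
  r2 <- gene_min_p(c("x1", "x2"), character(0), p, pos)
  expect_equal(r2$min_p, 0.001)
  # single-SNP identity
  expect_equal(gene_min_p("x2", character(0), p, pos)$min_p, 0.7)
  # position tie-break
  p3 <- c(s2 = 0.1, s1 = 0.1)
  pos3 <- c(s2 = 10, s1 = 50)
  expect_equal(gene_min_p(c("s2", "s1"), character(0), p3, pos3)$representative_snp,
               "s2")
  expect_error(gene_min_p(character(0), character(0), p, pos), "no mapped")
})

test_that("min-p monotonicity: adding a SNP never increases min_p", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    p <- setNames(runif(n), sprintf("s%d", 1:n))
    pos <- setNames(seq_len(n), names(p))
    ids <- names(p)
    before <- gene_min_p(ids[-n], character(0), p, pos)$min_p
    after <- gene_min_p(ids, character(0), p, pos)$min_p
    expect_lte(after, before)
  }
})

test_that("chisq_from_p matches the chi-square(1) quantile oracle", {
  expect_equal(chisq_from_p(1), 0)
  expect_equal(chisq_from_p(0.05), 3.841, tolerance = 1e-3)
  expect_equal(chisq_from_p(0.0455), 4.00, tolerance = 0.01 / 4)
  expect_error(chisq_from_p(0), "0, 1")
  expect_error(chisq_from_p(1.2), "0, 1")
  # two-sided inverse of the upper-tail CDF to 6 decimals on a 100-point grid
  grid <- seq(0.005, 0.995, length.out = 100)
  expect_equal(pchisq(chisq_from_p(grid), 1, lower.tail = FALSE), grid,
               tolerance = 1e-6)
})

test_that("genomewide proportion and informative flag use strict thresholds", {
  snps <- data.frame(p_value = c(0.01, 0.2, 0.04, 0.6))
  expect_equal(genomewide_significant_proportion(snps, 0.05), 0.5)
  expect_equal(genomewide_significant_proportion(data.frame(p_value = c(0.5, 0.9))), 0)
  expect_error(genomewide_significant_proportion(data.frame(p_value = numeric(0))),
               "empty")
  expect_true(informative_flag(0.2, 0.102))
  expect_false(informative_flag(0.1, 0.102))
  expect_false(informative_flag(0.102, 0.102))  # exactly at the average: not informative
})

test_that("adjusted_gene_score matches its resampling contract", {
  set.seed(5)
  pool <- runif(2000)
  # min_p below every null minimum: rank floor 1/(B+1)
  r <- adjusted_gene_score(min(pool) / 2, 5, pool, B = 200, seed = 1)
  expect_equal(r$adjusted_p, 1 / 201)
  expect_equal(r$gene_score, chisq_from_p(1 / 201))
  # n_snps = 1: adjusted_p converges to the pool ECDF at min_p
  for (q in c(0.1, 0.5, 0.9)) {
    r1 <- adjusted_gene_score(q, 1, pool, B = 10000, seed = 2)
    expect_lt(abs(r1$adjusted_p - mean(pool <= q)), 0.01)
  }
  expect_error(adjusted_gene_score(0.5, 10, runif(5), B = 100), "pool")
  # monotone in min_p at fixed size
  mp <- sort(runif(20))
  adj <- vapply(mp, function(x) adjusted_gene_score(x, 3, pool, B = 500,
                                                    seed = 7)$adjusted_p, 0)
  expect_true(all(diff(adj) >= 0))
})

test_that("adjusted_p of uniform-minimum genes is calibrated (KS < 0.05)", {
  set.seed(17)
  pool <- runif(20000)
  n_genes <- 2000
  sizes <- sample(1:20, n_genes, replace = TRUE)
  min_p <- vapply(seq_len(n_genes),
                  function(i) min(pool[sample.int(length(pool), sizes[i])]), 0)
  adj <- asmpath:::.adjusted_scores_batch(min_p, sizes, pool, B = 2000, seed = 23)
  ks <- suppressWarnings(ks.test(adj, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("score_genes assembles a consistent gene table", {
  st <- generate_study(scaled_config(19))
  pairs <- filter_asm_pairs(st$asm_pairs)
  gt <- score_genes(st$snps, st$genes, pairs, score_perms = 200, seed = 4)
  expect_true(all(gt$n_snps >= 1))
  expect_equal(gt$prop_significant, gt$n_significant_snps / gt$n_snps)
  expect_true(all(gt$min_p_all <= gt$min_p + 1e-15))
  expect_true(all(gt$adjusted_p > 0 & gt$adjusted_p <= 1))
  expect_equal(gt$gene_score, chisq_from_p(gt$adjusted_p))
  # partition property: ASM and non-ASM together cover all mapped genes
  expect_equal(sum(gt$is_asm) + sum(!gt$is_asm), nrow(gt))
  # ASM genes with in-gene ASM SNPs never use a non-ASM SNP for min_p
  asm_snps <- unique(pairs$snp_id)
  with_asm <- gt$is_asm & gt$n_asm_snps > 0
  expect_true(all(gt$representative_snp[with_asm] %in% asm_snps))
  # raw_chisq switch uses the unadjusted min-p statistic
  gt2 <- score_genes(st$snps, st$genes, pairs, score_perms = 200, seed = 4,
                     gene_stat = "raw_chisq")
  expect_equal(gt2$gene_score, chisq_from_p(gt2$min_p))
})
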