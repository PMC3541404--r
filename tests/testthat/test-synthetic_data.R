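test_that("generate_study is bit-identical under one seed and emits valid formats", {
  cfg <- scaled_config(7)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)
  dir <- withr::local_tempdir()
  simulate_study(cfg, dir)
  snps <- suppressMessages(read_assoc(file.path(dir, "assoc.txt")))
  genes <- read_gene_table(file.path(dir, "genes.bed"))
  pairs <- read_asm_pairs(file.path(dir, "asm_pairs.tsv"))
  sets <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(nrow(snps), nrow(a$snps))
  expect_equal(genes$start, a$genes$start)
  expect_equal(nrow(pairs), nrow(a$asm_pairs))
  expect_equal(length(sets), 60L)
  expect_equal(snps$p_value, a$snps$p_value, tolerance = 1e-12)
})

test_that("null p-values are uniform and the background spike hits its target", {
  st <- generate_study(scaled_config(11, bg = 0.05))
  n <- nrow(st$snps)
  expect_gt(n, 10000)
  frac <- mean(st$snps$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # spiked background reaches the real-cohort ~0.11 fraction
  st2 <- generate_study(scaled_config(11, bg = 0.11))
  frac2 <- mean(st2$snps$p_value < 0.05)
  expect_lt(abs(frac2 - 0.11), 3 * sqrt(0.11 * 0.89 / n) + 0.005)
})

test_that("ASM gene count is exact by construction and routes both exist", {
  st <- generate_study(scaled_config(3))
  tr <- st$truth$genes
  expect_equal(sum(tr$is_asm), round(0.13 * 2000))
  expect_true(any(tr$asm_route == "asm_snp_in_gene"))
  expect_true(any(tr$asm_route == "cpg_target"))
  # constructed truth agrees with the analysis-side partition
  mapping <- map_snps_to_genes(st$snps, st$genes)
  sets <- build_asm_gene_sets(mapping, filter_asm_pairs(st$asm_pairs))
  m <- match(sets$gene_id, tr$gene_id)
  expect_equal(sets$is_asm, tr$is_asm[m])
  expect_equal(sets$asm_route[sets$asm_route != "both"],
               tr$asm_route[m][sets$asm_route != "both"])
})

test_that("signal injection concentrates in ASM SNPs of enriched members", {
  enr <- list(list(index = 2, noncentrality = 20, asm_concentration = 1))
  st <- generate_study(scaled_config(5, enriched = enr))
  tr <- st$truth$genes
  hit <- !is.na(tr$signal_pathway)
  expect_setequal(tr$gene_id[hit], st$pathways[[2]])
  expect_true(st$truth$pathways$enriched[2])
  # with concentration 1, inflated SNPs of route-1 ASM member genes are ASM SNPs
  asm_members <- tr$gene_id[hit & tr$asm_route == "asm_snp_in_gene"]
  if (length(asm_members)) {
    asm_snps <- unique(st$asm_pairs$snp_id)
    infl <- tr$inflated_snp[match(asm_members, tr$gene_id)]
    expect_true(all(infl %in% asm_snps))
  }
  # enriched members carry smaller p-values than the null background
  p_mem <- st$snps$p_value[st$snps$snp_id %in% tr$inflated_snp[hit]]
  expect_lt(median(p_mem), 0.01)
})

test_that("generate_null_scores matches chi-square(1) moments and is seeded", {
  x <- generate_null_scores(100000, seed = 42)
  expect_identical(x, generate_null_scores(100000, seed = 42))
  expect_gt(mean(x), 0.98); expect_lt(mean(x), 1.02)
  expect_gt(var(x), 1.9); expect_lt(var(x), 2.1)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_study_config(n_genes = 50, pathway_size = c(10, 100)),
               "infeasible")
  expect_error(synthetic_study_config(asm_gene_fraction = 1.2))
  expect_error(synthetic_study_config(
    enriched_pathways = list(list(index = 9999, noncentrality = 1,
                                  asm_concentration = 0.5))))
})
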