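test_that("filter_pathways_by_size uses mapped-list sizes with inclusive bounds", {
  mapped <- sprintf("g%03d", 1:400)
  sets <- list(P9 = mapped[1:9], P10 = mapped[1:10], P380 = mapped[1:380],
               P381 = mapped[1:381])
  keep <- filter_pathways_by_size(sets, mapped)
  expect_named(keep, c("P10", "P380"))
  # size is measured after mapping: 200 database genes, only 8 mapped
  big <- list(PBIG = c(mapped[1:8], sprintf("x%d", 1:192)))
  expect_length(filter_pathways_by_size(big, mapped), 0L)
  expect_length(filter_pathways_by_size(list(), mapped), 0L)
})

test_that("apply_weights multiplies by subset weights and validates labels", {
  w <- list(w_asm = 1.5, w_nonasm = 0.75)
  scores <- c(A = 4, B = 2)
  lab <- c(A = TRUE, B = FALSE)
  expect_equal(apply_weights(scores, lab, w), c(A = 6, B = 1.5))
  expect_equal(apply_weights(scores, lab, list(w_asm = 1, w_nonasm = 1)), scores)
  expect_equal(apply_weights(c(A = 0, B = 0), lab, w), c(A = 0, B = 0))
  expect_error(apply_weights(c(A = 1, Z = 2), lab, w), "label")
})

test_that("enrichment_score reproduces the hand running-sum example", {
  scores <- c(g1 = 9, g2 = 4, g3 = 1, g4 = 0)
  # members at ranks 1 and 3: running sums 0.9, 0.4, 0.5, 0.0
  expect_equal(enrichment_score(c("g1", "g3"), scores), 0.9)
  # one member holds all the mass
  scores2 <- c(a = 5, b = 0, c = 0)
  expect_equal(enrichment_score("a", scores2), 1.0)
  # degenerate: zero member mass
  expect_equal(enrichment_score("b", scores2, c(b = 0)), 0)
  expect_error(enrichment_score(names(scores), scores), "members")
})

test_that("ES is invariant under positive rescaling and bounded in (-1, 1]", {
  set.seed(41)
  for (i in 1:40) {
    N <- sample(5:20, 1)
    scores <- setNames(rchisq(N, 1), sprintf("g%02d", 1:N))
    mem <- sample(names(scores), sample(1:(N - 1), 1))
    es <- enrichment_score(mem, scores)
    expect_gt(es, -1); expect_lte(es, 1 + 1e-12)
    expect_equal(enrichment_score(mem, scores * 7.3,
                                  member_weighted_scores = scores[mem] * 7.3), es)
  }
})

test_that("sum statistics are exact and strictly increasing in any member score", {
  expect_equal(sum_statistic(c(6, 1.5, 0)), 7.5)
  expect_equal(sum_square_statistic(c(6, 1.5, 0)), 38.25)
  x <- 3.2
  expect_equal(c(sum_statistic(x), sum_square_statistic(x)), c(x, x^2))
  set.seed(43)
  v <- rchisq(6, 1)
  for (j in seq_along(v)) {
    v2 <- v; v2[j] <- v2[j] + 0.5
    expect_gt(sum_statistic(v2), sum_statistic(v))
    expect_gt(sum_square_statistic(v2), sum_square_statistic(v))
  }
})

test_that("add-one empirical p-values follow the rank-count definition", {
  # observed 5 among permuted {1,2,3,10}: (1 + 1) / (4 + 1)
  expect_equal(oracle_empirical_p(5, c(1, 2, 3, 10)), 0.4)
  gt <- make_gene_table(20, seed = 2)
  sets <- list(GO_X = gt$gene_id[1:6])
  perms <- lapply(1:4, function(i) sample(nrow(gt)))
  pr <- permutation_pvalues(gt, sets, .perms = perms)
  for (col in colnames(pr$observed)) {
    st_perm <- vapply(perms, function(pi) {
      gt2 <- gt
      gt2$gene_score <- gt$gene_score[pi]
      gt2$is_informative <- gt$is_informative[pi]
      permutation_pvalues(gt2, sets, .perms = list(seq_len(nrow(gt))))$observed[, col]
    }, 0)
    expect_equal(unname(pr$empirical_p[, col]),
                 oracle_empirical_p(unname(pr$observed[, col]), st_perm))
  }
  expect_error(permutation_pvalues(gt, sets, B = 50), "at least 100")
})

test_that("all six statistics match the straight-line oracle across permutations", {
  set.seed(47)
  for (rep in 1:20) {
    N <- sample(8:20, 1)
    gt <- data.frame(gene_id = sprintf("g%02d", sample(N)),
                     gene_score = rchisq(N, 1),
                     is_informative = runif(N) < 0.4,
                     is_asm = runif(N) < 0.4, stringsAsFactors = FALSE)
    sets <- lapply(1:3, function(i) sample(gt$gene_id, sample(2:(N - 2), 1)))
    names(sets) <- sprintf("P%d", 1:3)
    perms <- lapply(1:10, function(i) sample(N))
    pr <- permutation_pvalues(gt, sets, .perms = perms)
    oracle_obs <- oracle_stats(gt$gene_score, gt$is_informative, gt$is_asm,
                               gt$gene_id, sets)
    expect_equal(unname(t(pr$observed)), unname(oracle_obs))
    # empirical p against oracle permutation replay
    exceed <- matrix(0, 3, 6, dimnames = dimnames(pr$observed))
    for (pi in perms) {
      st <- oracle_stats(gt$gene_score[pi], gt$is_informative[pi], gt$is_asm,
                         gt$gene_id, sets)
      exceed <- exceed + (t(st) >= pr$observed)
    }
    expect_equal(pr$empirical_p, (1 + exceed) / (1 + length(perms)))
  }
})

test_that("bh_adjust matches the hand step-up example and p.adjust", {
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in input ranks
  }
})

test_that("significant_pathways applies the FDR rule and records triggers", {
  gt <- make_gene_table(40, seed = 8)
  sets <- lapply(1:3, function(i) sample(gt$gene_id, 10))
  names(sets) <- sprintf("GO_P%d", 1:3)
  res <- pathway_analysis(gt, sets, B = 100, seed = 3, min_size = 5, max_size = 50)
  res$sumst_weighted_bh <- c(0.009, 0.5, 0.5)
  res$gsea_weighted_bh <- c(0.5, 0.5, 0.5)
  sel <- significant_pathways(res, 0.01)
  expect_equal(sel$pathway, res$pathway[1])
  expect_match(sel$triggered_by, "sumst_weighted")
  res$sumst_weighted_bh <- rep(0.5, 3)
  expect_equal(nrow(significant_pathways(res, 0.01)), 0L)
  expect_error(significant_pathways(res, 0), "fdr")
})

test_that("pathway_analysis output respects invariants and weighting modes", {
  gt <- make_gene_table(60, seed = 10)
  sets <- lapply(1:5, function(i) sample(gt$gene_id, sample(8:20, 1)))
  names(sets) <- sprintf("GO_P%d", 1:5)
  res <- pathway_analysis(gt, sets, B = 150, seed = 6, min_size = 5, max_size = 50)
  p_cols <- grep("_p$", names(res), value = TRUE)
  for (col in p_cols) {
    expect_true(all(res[[col]] >= 1 / 151))
    bh <- sub("_p$", "_bh", col)
    expect_true(all(res[[bh]] >= res[[col]] - 1e-12))
  }
  expect_true(all(res$genes_on_list <= res$total_genes))
  off <- pathway_analysis(gt, sets, B = 150, seed = 6, min_size = 5,
                          max_size = 50, weighting = "off")
  expect_false(any(grepl("weighted_stat", names(off)) &
                   !grepl("unweighted_stat", names(off))))
  expect_equal(off$sumst_unweighted_p, res$sumst_unweighted_p)
})
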