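# Independent straight-line oracles used to cross-check the package's
# vectorized implementations. Kept deliberately naive: plain loops, no
# shared code with R/.

# weighting rule, re-implemented directly from the printed branches
oracle_weight_pair <- function(n, m, k_n, k_m) {
  if (n == 0 || m == 0) return(c(1, 1))
  Rn <- k_n / n
  Rm <- k_m / m
  if (k_m == 0 && k_n > 0) {
    cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    w <- 1
    for (c in cuts) if (Rn >= c) w <- w + 1
    return(c(w, 1))
  }
  if (Rn > Rm) {
    H <- 2 / (1 / Rn + 1 / Rm)
    return(c(Rn / H, Rm / H))
  }
  c(1, 1)
}

# running-sum enrichment score, literal loop over all N ranked genes
oracle_es <- function(all_scores, members, member_weighted) {
  N <- length(all_scores)
  ord <- names(all_scores)[order(-all_scores, names(all_scores))]
  NR <- sum(member_weighted[members])
  if (NR == 0) return(0)
  dec <- 1 / (N - length(members))
  run <- 0
  best <- -Inf
  for (g in ord) {
    if (g %in% members) run <- run + member_weighted[[g]] / NR
    else run <- run - dec
    best <- max(best, run)
  }
  best
}

# all six statistics for one assignment of scores/flags to genes
oracle_stats <- function(score, informative, is_asm, gene_id, member_ids) {
  names(score) <- names(informative) <- names(is_asm) <- gene_id
  sapply(member_ids, function(mem) {
    s <- score[mem]
    a <- is_asm[mem]
    inf <- informative[mem]
    w <- oracle_weight_pair(sum(a), sum(!a), sum(inf & a), sum(inf & !a))
    ws <- ifelse(a, w[1], w[2]) * s
    c(gsea_weighted = oracle_es(score, mem, ws),
      gsea_unweighted = oracle_es(score, mem, s),
      sumst_weighted = sum(ws), sumst_unweighted = sum(s),
      sumsq_weighted = sum(ws^2), sumsq_unweighted = sum(s^2))
  })
}

# add-one empirical p
oracle_empirical_p <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}

# exact hypergeometric upper tail by enumeration (universes <= ~12)
oracle_hyper_tail <- function(overlap, term, universe, query) {
  p <- 0
  for (k in overlap:min(term, query)) {
    p <- p + choose(term, k) * choose(universe - term, query - k) /
      choose(universe, query)
  }
  p
}

# tiny deterministic fixture shared by io/postprocess tests
write_fixture_files <- function(dir) {
  assoc <- c("CHR SNP BP P CHISQ",
             "1 rs1 1000 0.02 5.41",
             "1 rs2 12000 0.5 0.45",
             "2 rs3 5000 0.001 10.8",
             "2 rs4 5500 NA NA",
             "23 rsX 500 0.1 2.7")
  writeLines(assoc, file.path(dir, "assoc.txt"))
  bed <- c("chr1\t999\t2000\tGENE1", "chr2\t4000\t6000\tGENE2")
  writeLines(bed, file.path(dir, "genes.bed"))
  pairs <- c(paste(c("snp_id", "snp_chromosome", "snp_position", "cpg_chromosome",
                     "cpg_position", "target_gene_id", "mode", "p_value"),
                   collapse = "\t"),
             "rs1\t1\t1000\t1\t500\tGENE1\tcis\t0.01",
             "rs3\t2\t5000\t7\t100\tGENE1\ttrans\t0.02",
             "rs2\t1\t12000\t1\t13000\tGENE1\tcis\t0.2")
  writeLines(pairs, file.path(dir, "asm_pairs.tsv"))
  gmt <- c("GO_SET1\tdesc\tGENE1\tGENE2\tGENE1", "KEGG_SET2\tdesc\tGENE2")
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  dir
}

# small scored gene table for enrichment tests
make_gene_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             gene_score = rchisq(n, 1),
             is_informative = runif(n) < 0.3,
             is_asm = runif(n) < 0.3,
             stringsAsFactors = FALSE)
}

scaled_config <- function(seed, enriched = list(), bg = 0.05) {
  synthetic_study_config(
    n_genes = 2000, snps_per_gene = c(min = 1, max = 60, mean = 10),
    gene_length_bp = c(2000, 20000), n_pathways = 60,
    pathway_size = c(10, 50), enriched_pathways = enriched,
    background_alpha_fraction = bg, seed = seed)
}

run_scaled_study <- function(seed, enriched = list(), bg = 0.05,
                             score_perms = 500, pathway_perms = 500) {
  st <- generate_study(scaled_config(seed, enriched, bg))
  gt <- score_genes(st$snps, st$genes, filter_asm_pairs(st$asm_pairs),
                    score_perms = score_perms, seed = seed + 1000L)
  res <- pathway_analysis(gt, st$pathways, B = pathway_perms, seed = seed + 2000L)
  list(study = st, gene_table = gt, results = res)
}
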