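# Synthetic-study generator. Emulates the scale of the real bipolar-disorder
# GWA inputs (hundreds of thousands of SNPs on ~15,000 mapped autosomal
# genes, ~11% of SNPs below 0.05, ~13% ASM genes, MSigDB-style pathways of
# 10-380 genes) with controllable null/alternative structure, so that every
# downstream stage can be exercised without controlled-access data.

# Derived per-component RNG streams from a single master seed (kept < 2^31).
.seed_stream <- function(seed, k) set.seed((as.integer(seed) %% 10000000L) * 100L + k)

# sample k elements from a vector, immune to R's scalar-x expansion
.sample_vec <- function(x, k) x[sample.int(length(x), k)]

#' Configuration for a synthetic GWAS pathway study
#'
#' Defaults are full real-study scale: 15,000 genes averaging 13 SNPs each
#' (~195k SNPs), 13% ASM genes, 4,000 pathways of 10-380 genes and a
#' background significant-SNP fraction of 0.11. Scale down (fewer genes /
#' pathways) for unit testing.
#'
#' @param n_genes number of genes laid out on chromosomes 1..22.
#' @param snps_per_gene named vector `c(min=, max=, mean=)`: SNP counts per
#'   gene follow a geometric distribution on 1,2,... with the given mean,
#'   truncated to `[min, max]`.
#' @param gene_length_bp range (min, max) of gene lengths in bp.
#' @param asm_gene_fraction fraction of genes flagged ASM by construction.
#' @param asm_snps_per_asm_gene range of ASM SNPs given to each ASM gene.
#' @param n_pathways number of gene sets to simulate.
#' @param pathway_size range of pathway sizes (genes per set).
#' @param enriched_pathways list of `list(index=, noncentrality=,
#'   asm_concentration=)` descriptors: each member gene of pathway `index`
#'   has one SNP whose chi-square statistic is drawn from a noncentral
#'   chi-square(1, ncp = noncentrality); in ASM genes that SNP is an ASM
#'   SNP with probability `asm_concentration`.
#' @param background_alpha_fraction target fraction of SNPs with p < 0.05
#'   (0.05 means a pure uniform null; larger values spike a matching
#'   fraction of SNPs, emulating the polygenic background of real data).
#' @param seed master seed; all component streams derive from it.
#' @return object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_genes = 15000,
                                   snps_per_gene = c(min = 1, max = 120, mean = 13),
                                   gene_length_bp = c(5000, 100000),
                                   asm_gene_fraction = 0.13,
                                   asm_snps_per_asm_gene = c(1, 4),
                                   n_pathways = 4000,
                                   pathway_size = c(10, 380),
                                   enriched_pathways = list(),
                                   background_alpha_fraction = 0.11,
                                   seed = 1L) {
  stopifnot(n_genes >= 1, n_pathways >= 1,
            length(pathway_size) == 2, pathway_size[1] >= 1,
            pathway_size[1] <= pathway_size[2],
            asm_gene_fraction >= 0, asm_gene_fraction <= 1,
            background_alpha_fraction >= 0, background_alpha_fraction <= 1,
            snps_per_gene[["min"]] >= 1,
            snps_per_gene[["min"]] <= snps_per_gene[["mean"]],
            snps_per_gene[["mean"]] <= snps_per_gene[["max"]],
            gene_length_bp[1] >= snps_per_gene[["max"]],
            gene_length_bp[1] <= gene_length_bp[2])
  if (pathway_size[2] > n_genes) {
    stop("infeasible config: pathway_size exceeds the gene universe", call. = FALSE)
  }
  for (e in enriched_pathways) {
    stopifnot(e$index >= 1, e$index <= n_pathways, e$noncentrality >= 0,
              e$asm_concentration >= 0, e$asm_concentration <= 1)
  }
  structure(list(n_genes = as.integer(n_genes), snps_per_gene = snps_per_gene,
                 gene_length_bp = as.integer(gene_length_bp),
                 asm_gene_fraction = asm_gene_fraction,
                 asm_snps_per_asm_gene = as.integer(asm_snps_per_asm_gene),
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 enriched_pathways = enriched_pathways,
                 background_alpha_fraction = background_alpha_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Generate a complete synthetic study
#'
#' Produces in-memory tables in the exact shapes the readers return: SNP
#' association records, gene coordinates, ASM SNP-CpG pairs, pathways, and
#' a truth table recording where signal was injected. Null SNP p-values are
#' i.i.d. uniform(0,1); SNPs of enriched-pathway member genes carry a
#' noncentral chi-square(1) statistic; genes are laid out non-overlapping
#' (gaps wider than twice the 5 kb mapping window) on chromosomes 1..22.
#' The same seed reproduces the bundle bit for bit.
#'
#' @param config a [synthetic_study_config()].
#' @return list with elements `snps`, `genes`, `asm_pairs`, `pathways`,
#'   `truth` (list of `genes` and `pathways` data.frames) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  ng <- config$n_genes

  # --- gene layout -----------------------------------------------------
  .seed_stream(config$seed, 1L)
  gene_id <- sprintf("G%05d", seq_len(ng))
  chrom <- rep(1:22, length.out = ng)
  len <- sample(config$gene_length_bp[1]:config$gene_length_bp[2], ng, replace = TRUE)
  start <- integer(ng)
  gap <- 20001L  # > 2 * 5 kb window: genes never share SNPs
  for (c in 1:22) {
    i <- which(chrom == c)
    start[i] <- cumsum(c(gap, utils::head(len[i], -1) + gap))
  }
  genes <- data.frame(gene_id = gene_id, chromosome = chrom,
                      start = start, end = start + len - 1L,
                      stringsAsFactors = FALSE)

  # --- SNP placement ---------------------------------------------------
  .seed_stream(config$seed, 2L)
  spg <- config$snps_per_gene
  nsnp <- pmin(pmax(1L + stats::rgeom(ng, prob = 1 / spg[["mean"]]),
                    as.integer(spg[["min"]])), as.integer(spg[["max"]]))
  snp_gene <- rep(seq_len(ng), nsnp)
  offs <- unlist(lapply(seq_len(ng), function(i) sort(sample.int(len[i], nsnp[i]))),
                 use.names = FALSE)
  snps <- data.frame(snp_id = sprintf("rs%07d", seq_along(snp_gene)),
                     chromosome = chrom[snp_gene],
                     position = start[snp_gene] + offs - 1L,
                     stringsAsFactors = FALSE)
  snp_by_gene <- split(seq_len(nrow(snps)), snp_gene)

  # --- ASM genes and SNP-CpG pairs ------------------------------------
  .seed_stream(config$seed, 3L)
  nd <- round(config$asm_gene_fraction * ng)
  asm_idx <- sort(sample.int(ng, nd))
  # ~10% of ASM genes are members only through the CpG-target route
  n2 <- if (nd >= 10) floor(0.1 * nd) else 0L
  route2 <- if (n2 > 0) sample(asm_idx, n2) else integer(0)
  route1 <- setdiff(asm_idx, route2)
  if (!length(route1) && length(route2)) { route1 <- route2; route2 <- integer(0) }
  # a cpg_target-only gene needs a donor ASM SNP on another chromosome
  ok2 <- vapply(route2, function(i) any(chrom[route1] != chrom[i]), TRUE)
  route1 <- sort(c(route1, route2[!ok2]))
  route2 <- route2[ok2]

  asm_snp_rows <- integer(0)
  pair_rows <- list()
  rng <- config$asm_snps_per_asm_gene
  for (i in route1) {
    rows <- snp_by_gene[[as.character(i)]]
    k <- min(length(rows), .sample_vec(rng[1]:rng[2], 1L))
    pick <- .sample_vec(rows, k)
    asm_snp_rows <- c(asm_snp_rows, pick)
    off <- sample(c(-100000:-1, 1:100000), k, replace = TRUE)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      snp_id = snps$snp_id[pick], snp_chromosome = snps$chromosome[pick],
      snp_position = snps$position[pick],
      cpg_chromosome = snps$chromosome[pick],
      cpg_position = pmax(1L, snps$position[pick] + off),
      target_gene_id = gene_id[i], mode = "cis",
      p_value = stats::runif(k) * 0.05, stringsAsFactors = FALSE)
  }
  for (i in route2) {
    src <- route1[chrom[route1] != chrom[i]]
    s <- .sample_vec(src, 1L)
    srow <- snp_by_gene[[as.character(s)]][1L]
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      snp_id = snps$snp_id[srow], snp_chromosome = snps$chromosome[srow],
      snp_position = snps$position[srow],
      cpg_chromosome = chrom[i],
      cpg_position = as.integer(start[i] + len[i] %/% 2L),
      target_gene_id = gene_id[i], mode = "trans",
      p_value = stats::runif(1) * 0.05, stringsAsFactors = FALSE)
  }
  # decoy pairs above the 0.05 selection threshold, to exercise filtering
  if (length(asm_snp_rows)) {
    ndec <- max(1L, round(0.05 * length(asm_snp_rows)))
    pick <- .sample_vec(asm_snp_rows, min(ndec, length(asm_snp_rows)))
    g <- snp_gene[pick]
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      snp_id = snps$snp_id[pick], snp_chromosome = snps$chromosome[pick],
      snp_position = snps$position[pick],
      cpg_chromosome = snps$chromosome[pick],
      cpg_position = snps$position[pick] + 500L,
      target_gene_id = gene_id[g], mode = "cis",
      p_value = 0.05 + stats::runif(length(pick)) * 0.95,
      stringsAsFactors = FALSE)
  }
  asm_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(snp_id = character(0), snp_chromosome = integer(0),
               snp_position = integer(0), cpg_chromosome = integer(0),
               cpg_position = integer(0), target_gene_id = character(0),
               mode = character(0), p_value = numeric(0))
  rownames(asm_pairs) <- NULL
  is_asm_snp <- logical(nrow(snps))
  is_asm_snp[asm_snp_rows] <- TRUE

  # --- pathways --------------------------------------------------------
  .seed_stream(config$seed, 4L)
  np <- config$n_pathways
  src_cycle <- rep(c("GO", "KEGG", "REACTOME", "BIOCARTA", "LIT"), length.out = np)
  pnames <- sprintf("%s_SYNTH_%04d", src_cycle, seq_len(np))
  sizes <- sample(config$pathway_size[1]:config$pathway_size[2], np, replace = TRUE)
  pathways <- lapply(sizes, function(s) sample(gene_id, s))
  names(pathways) <- pnames
  attr(pathways, "description") <- stats::setNames(rep("synthetic", np), pnames)
  attr(pathways, "source") <- stats::setNames(vapply(pnames, .pathway_source, ""), pnames)

  # --- p-values: null + background spike -------------------------------
  .seed_stream(config$seed, 5L)
  p <- stats::runif(nrow(snps))
  bg <- config$background_alpha_fraction
  if (bg > 0.05) {
    s <- (bg - 0.05) / 0.95
    spike <- stats::runif(nrow(snps)) < s
    p[spike] <- stats::runif(sum(spike)) * 0.05
  }

  # --- signal injection ------------------------------------------------
  .seed_stream(config$seed, 6L)
  gene_signal_pathway <- rep(NA_character_, ng)
  gene_inflated_snp <- rep(NA_character_, ng)
  enr_idx <- vapply(config$enriched_pathways, function(e) as.integer(e$index), 0L)
  for (e in config$enriched_pathways) {
    members <- match(pathways[[e$index]], gene_id)
    for (i in members) {
      rows <- snp_by_gene[[as.character(i)]]
      asm_rows <- rows[is_asm_snp[rows]]
      cand <- if (length(asm_rows) && stats::runif(1) < e$asm_concentration)
        asm_rows else rows
      pick <- .sample_vec(cand, 1L)
      x <- stats::rchisq(1L, df = 1, ncp = e$noncentrality)
      p_new <- stats::pchisq(x, df = 1, lower.tail = FALSE)
      if (is.na(gene_inflated_snp[i]) || p_new < p[pick]) {
        p[pick] <- min(p[pick], p_new)
        gene_signal_pathway[i] <- pnames[e$index]
        gene_inflated_snp[i] <- snps$snp_id[pick]
      }
    }
  }
  snps$p_value <- pmax(p, .Machine$double.xmin)
  snps$chi_square <- stats::qchisq(snps$p_value, df = 1, lower.tail = FALSE)

  truth <- list(
    genes = data.frame(gene_id = gene_id, chromosome = chrom,
                       is_asm = seq_len(ng) %in% asm_idx,
                       asm_route = ifelse(seq_len(ng) %in% route2, "cpg_target",
                                   ifelse(seq_len(ng) %in% route1, "asm_snp_in_gene",
                                          "none")),
                       n_snps = nsnp,
                       signal_pathway = gene_signal_pathway,
                       inflated_snp = gene_inflated_snp,
                       stringsAsFactors = FALSE),
    pathways = data.frame(pathway = pnames, size = sizes,
                          enriched = seq_len(np) %in% enr_idx,
                          noncentrality = vapply(seq_len(np), function(i) {
                            j <- match(i, enr_idx)
                            if (is.na(j)) 0 else config$enriched_pathways[[j]]$noncentrality
                          }, 0),
                          stringsAsFactors = FALSE))

  list(snps = snps, genes = genes, asm_pairs = asm_pairs,
       pathways = pathways, truth = truth, config = config)
}

#' Generate i.i.d. null gene scores
#'
#' Unit-test shortcut that bypasses the SNP level: seeded i.i.d. 1-df
#' chi-square draws on the gene-score scale.
#'
#' @param n_genes number of scores.
#' @param seed RNG seed.
#' @return numeric vector of length `n_genes`.
#' @export
generate_null_scores <- function(n_genes, seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(as.integer(seed))
  stats::rchisq(n_genes, df = 1)
}

#' Write a synthetic study bundle to disk
#'
#' Emits the exact formats the readers ingest: `assoc.txt` (PLINK .assoc
#' dialect), `genes.bed` (BED4, 0-based half-open), `asm_pairs.tsv`,
#' `pathways.gmt`, plus `truth_genes.tsv` and `truth_pathways.tsv`.
#'
#' @param config a [synthetic_study_config()].
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
simulate_study <- function(config, dir) {
  study <- generate_study(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(assoc = file.path(dir, "assoc.txt"),
             genes = file.path(dir, "genes.bed"),
             asm_pairs = file.path(dir, "asm_pairs.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_pathways = file.path(dir, "truth_pathways.tsv"))
  assoc <- data.frame(CHR = study$snps$chromosome, SNP = study$snps$snp_id,
                      BP = study$snps$position,
                      CHISQ = .fmt_real(study$snps$chi_square),
                      P = .fmt_real(study$snps$p_value))
  utils::write.table(assoc, paths[["assoc"]], sep = " ", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = paste0("chr", study$genes$chromosome),
                    start = study$genes$start - 1L, end = study$genes$end,
                    name = study$genes$gene_id)
  utils::write.table(bed, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_tsv(study$asm_pairs, paths[["asm_pairs"]])
  write_gmt(study$pathways, paths[["gmt"]])
  .write_tsv(study$truth$genes, paths[["truth_genes"]])
  .write_tsv(study$truth$pathways, paths[["truth_pathways"]])
  invisible(paths)
}
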