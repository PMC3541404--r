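# Gene-level scoring: SNP-to-gene mapping, ASM / non-ASM partition, min-p
# statistics, gene-size adjustment by pool resampling, informative flags.

#' Map SNPs to gene regions
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' `window_bp` of either gene end, boundaries inclusive. A SNP may map to
#' several overlapping genes; genes with no mapped SNP are absent from the
#' result and from all downstream analysis.
#'
#' @param snps data.frame from [read_assoc()].
#' @param genes data.frame from [read_gene_table()].
#' @param window_bp window size in bp on each side of the gene (default 5000).
#' @return named list: `gene_id` -> character vector of SNP ids, ordered by
#'   position.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 5000) {
  idx <- .map_snp_indices(snps, genes, window_bp)
  lapply(idx, function(i) snps$snp_id[i])
}

# same mapping as integer row indices into `snps` (ordered by position)
.map_snp_indices <- function(snps, genes, window_bp = 5000) {
  stopifnot(window_bp >= 0)
  gr_genes <- GenomicRanges::GRanges(
    genes$chromosome,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(window_bp)),
                     genes$end + as.integer(window_bp)))
  gr_snps <- GenomicRanges::GRanges(
    snps$chromosome, IRanges::IRanges(snps$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  q <- S4Vectors::queryHits(hits)[order(S4Vectors::subjectHits(hits),
                                        snps$position[S4Vectors::queryHits(hits)])]
  s <- sort(S4Vectors::subjectHits(hits))
  mapping <- split(q, genes$gene_id[s])
  # keep the gene-table order
  mapping[order(match(names(mapping), genes$gene_id))]
}

#' Partition mapped genes into ASM and non-ASM sets
#'
#' A gene belongs to the ASM set when (1) at least one of its mapped SNPs
#' appears as a regulating SNP in the (already filtered) ASM pair list, or
#' (2) the gene is the target of a pair, i.e. it contains a CpG site that is
#' regulated by an ASM-list SNP. The membership route is recorded so the
#' min-p fallback for CpG-target-only genes stays auditable. Pairs whose
#' target gene is not among the mapped genes are ignored with a warning.
#'
#' @param mapping named list from [map_snps_to_genes()].
#' @param asm_pairs filtered pair table ([filter_asm_pairs()]).
#' @return data.frame with columns `gene_id`, `is_asm`, `asm_route`
#'   (`asm_snp_in_gene`, `cpg_target`, `both` or `none`).
#' @export
build_asm_gene_sets <- function(mapping, asm_pairs) {
  gene_ids <- names(mapping)
  asm_snps <- unique(asm_pairs$snp_id)
  via_snp <- vapply(mapping, function(s) any(s %in% asm_snps), TRUE)
  targets <- unique(asm_pairs$target_gene_id)
  unknown <- setdiff(targets, gene_ids)
  if (length(unknown)) {
    warning(sprintf("%d ASM pair target gene(s) absent from the mapped gene list; ignored",
                    length(unknown)), call. = FALSE)
  }
  via_target <- gene_ids %in% targets
  route <- ifelse(via_snp & via_target, "both",
           ifelse(via_snp, "asm_snp_in_gene",
           ifelse(via_target, "cpg_target", "none")))
  data.frame(gene_id = gene_ids, is_asm = via_snp | via_target,
             asm_route = route, stringsAsFactors = FALSE, row.names = NULL)
}

#' Minimum p-value of a gene
#'
#' For an ASM gene with at least one in-gene ASM-list SNP, the minimum is
#' taken over its ASM SNPs only; an ASM gene that is a member only through
#' the CpG-target route (no in-gene ASM SNP) falls back to the minimum over
#' all its SNPs, as does a non-ASM gene. Ties for the representative SNP
#' break by lowest position, then lexicographic SNP id.
#'
#' @param snp_ids mapped SNP ids of the gene (non-empty).
#' @param asm_snp_ids subset of `snp_ids` that are in the ASM list.
#' @param p named numeric vector, SNP id -> p-value.
#' @param position named numeric vector, SNP id -> position (for tie-breaks).
#' @return list with `min_p` and `representative_snp`.
#' @export
gene_min_p <- function(snp_ids, asm_snp_ids, p, position) {
  if (!length(snp_ids)) stop("gene has no mapped SNPs", call. = FALSE)
  use <- if (length(asm_snp_ids)) asm_snp_ids else snp_ids
  pv <- p[use]
  best <- use[pv == min(pv)]
  if (length(best) > 1L) best <- best[order(position[best], best)]
  list(min_p = unname(min(pv)), representative_snp = best[1L])
}

#' Inverse upper-tail 1-df chi-square transform
#'
#' Returns the chi-square(1) value whose upper-tail probability is `p`;
#' strictly decreasing in `p`, with `chisq_from_p(1) == 0`.
#'
#' @param p p-value(s) in (0, 1].
#' @return chi-square statistic(s).
#' @export
chisq_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Genome-wide proportion of significant SNPs
#'
#' Fraction of all analyzed SNPs (not only mapped ones) with p below
#' `alpha`; the reference against which per-gene informativeness is judged.
#'
#' @param snps data.frame with a `p_value` column.
#' @param alpha significance threshold, default 0.05.
#' @return scalar proportion.
#' @export
genomewide_significant_proportion <- function(snps, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(snps)) stop("empty SNP table", call. = FALSE)
  mean(snps$p_value < alpha)
}

#' Informative-gene flag
#'
#' A gene is informative when its proportion of significant SNPs strictly
#' exceeds the genome-wide proportion.
#'
#' @param prop_significant per-gene proportion(s) of SNPs with p < alpha.
#' @param genomewide_prop genome-wide reference proportion.
#' @return logical vector.
#' @export
informative_flag <- function(prop_significant, genomewide_prop) {
  prop_significant > genomewide_prop
}

# B null minima of `n_snps` p-values resampled without replacement from pool
.null_minima <- function(pool, n_snps, B) {
  np <- length(pool)
  vapply(seq_len(B), function(b) min(pool[sample.int(np, n_snps)]), numeric(1))
}

#' Gene-size adjusted score for one gene
#'
#' The null for a gene with `n_snps` SNPs is `B` minima of `n_snps`
#' p-values drawn without replacement from the pool of all analyzed SNP
#' p-values; the adjusted p-value is the add-one tail rank
#' `(1 + #\{null min <= min_p\}) / (1 + B)` and the gene score is the
#' chi-square(1) value at that upper-tail probability. This resampling
#' construction removes the advantage large genes enjoy under a plain
#' min-p statistic.
#'
#' @param min_p observed minimum p-value of the gene.
#' @param n_snps number of SNPs mapped to the gene.
#' @param pool numeric vector of all analyzed SNP p-values.
#' @param B number of resampling replicates (default 10000, minimum 100).
#' @param seed RNG seed.
#' @return list with `adjusted_p` and `gene_score`.
#' @export
adjusted_gene_score <- function(min_p, n_snps, pool, B = 10000, seed = 1L) {
  stopifnot(B >= 100, n_snps >= 1)
  if (length(pool) < n_snps) stop("pool smaller than the gene's SNP count", call. = FALSE)
  set.seed(as.integer(seed))
  nulls <- .null_minima(pool, n_snps, B)
  adjusted_p <- (1 + sum(nulls <= min_p)) / (1 + B)
  list(adjusted_p = adjusted_p, gene_score = chisq_from_p(adjusted_p))
}

# Batch version: one shared null-minima set per distinct SNP count.
.adjusted_scores_batch <- function(min_p, n_snps, pool, B, seed) {
  set.seed(as.integer(seed))
  adj <- numeric(length(min_p))
  for (s in sort(unique(n_snps))) {
    nulls <- sort(.null_minima(pool, s, B))
    i <- which(n_snps == s)
    adj[i] <- (1 + findInterval(min_p[i], nulls)) / (1 + B)
  }
  adj
}

#' Score all genes of a study
#'
#' End-to-end gene-level stage: maps SNPs to genes, partitions genes into
#' ASM / non-ASM sets, computes min-p with the ASM rule, the size-adjusted
#' score, significant-SNP proportions and informative flags.
#'
#' @param snps data.frame from [read_assoc()].
#' @param genes data.frame from [read_gene_table()].
#' @param asm_pairs filtered ASM pair table.
#' @param window_bp SNP-to-gene window (default 5000 bp).
#' @param snp_alpha per-SNP significance threshold (default 0.05).
#' @param score_perms resampling replicates for the size adjustment
#'   (default 10000).
#' @param seed RNG seed for the size adjustment.
#' @param gene_stat `"adjusted"` (default) uses the size-adjusted score as
#'   the gene statistic for pathway analysis; `"raw_chisq"` uses the
#'   chi-square transform of the raw min-p.
#' @return data.frame (one row per mapped gene): `gene_id`, `chromosome`,
#'   `start`, `end`, `n_snps`, `n_asm_snps`, `is_asm`, `asm_route`,
#'   `min_p`, `min_p_all`, `representative_snp`, `adjusted_p`,
#'   `gene_score`, `n_significant_snps`, `prop_significant`,
#'   `is_informative`. The SNP-id mapping is attached as attribute
#'   `mapping`, and the genome-wide significant proportion as
#'   `genomewide_prop`.
#' @export
score_genes <- function(snps, genes, asm_pairs, window_bp = 5000,
                        snp_alpha = 0.05, score_perms = 10000, seed = 1L,
                        gene_stat = c("adjusted", "raw_chisq")) {
  gene_stat <- match.arg(gene_stat)
  idx_map <- .map_snp_indices(snps, genes, window_bp)
  mapping <- lapply(idx_map, function(i) snps$snp_id[i])
  sets <- build_asm_gene_sets(mapping, asm_pairs)
  pvec <- snps$p_value
  posvec <- snps$position
  idvec <- snps$snp_id
  snp_is_asm <- idvec %in% unique(asm_pairs$snp_id)

  n <- length(mapping)
  min_p <- min_p_all <- numeric(n)
  rep_snp <- character(n)
  n_snps <- n_asm <- n_sig <- integer(n)
  for (i in seq_len(n)) {
    idx <- idx_map[[i]]
    pp <- pvec[idx]
    aflag <- snp_is_asm[idx]
    use <- if (sets$is_asm[i] && any(aflag)) which(aflag) else seq_along(idx)
    pu <- pp[use]
    mp <- min(pu)
    j <- use[pu == mp]
    if (length(j) > 1L) j <- j[order(posvec[idx[j]], idvec[idx[j]])]
    min_p[i] <- mp
    rep_snp[i] <- idvec[idx[j[1L]]]
    min_p_all[i] <- min(pp)
    n_snps[i] <- length(idx)
    n_asm[i] <- sum(aflag)
    n_sig[i] <- sum(pp < snp_alpha)
  }
  gw <- genomewide_significant_proportion(snps, snp_alpha)
  adj <- .adjusted_scores_batch(min_p, n_snps, snps$p_value, score_perms, seed)
  score <- if (gene_stat == "adjusted") chisq_from_p(adj) else chisq_from_p(min_p)

  gi <- match(names(mapping), genes$gene_id)
  out <- data.frame(gene_id = names(mapping),
                    chromosome = genes$chromosome[gi],
                    start = genes$start[gi], end = genes$end[gi],
                    n_snps = n_snps, n_asm_snps = n_asm,
                    is_asm = sets$is_asm, asm_route = sets$asm_route,
                    min_p = min_p, min_p_all = min_p_all,
                    representative_snp = rep_snp,
                    adjusted_p = adj, gene_score = score,
                    n_significant_snps = n_sig,
                    prop_significant = n_sig / n_snps,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$is_informative <- informative_flag(out$prop_significant, gw)
  attr(out, "mapping") <- mapping
  attr(out, "genomewide_prop") <- gw
  attr(out, "gene_stat") <- gene_stat
  out
}
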