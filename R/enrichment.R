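# Pathway statistics (GSEA enrichment score, sum-statistic,
# sum-square-statistic), weighted and unweighted, with gene-label
# permutation p-values and Benjamini-Hochberg FDR control.

#' Filter pathways on mapped-list size
#'
#' Keeps pathways whose number of genes present on the mapped gene list
#' lies in `[min_size, max_size]`; the defaults (10, 380) drop gene sets
#' that are too small to be stable or too broad to be interpretable.
#'
#' @param pathways named list of gene-id vectors.
#' @param mapped_genes character vector of mapped gene ids.
#' @param min_size,max_size inclusive size bounds (defaults 10 and 380).
#' @return the retained sublist (attributes `description`/`source` subset).
#' @export
filter_pathways_by_size <- function(pathways, mapped_genes, min_size = 10,
                                    max_size = 380) {
  stopifnot(min_size <= max_size)
  sz <- vapply(pathways, function(g) sum(g %in% mapped_genes), 0L)
  keep <- sz >= min_size & sz <= max_size
  out <- pathways[keep]
  for (a in c("description", "source")) {
    at <- attr(pathways, a)
    if (!is.null(at)) attr(out, a) <- at[names(out)]
  }
  out
}

#' Apply subset weights to gene scores
#'
#' Multiplies each ASM member's score by `w_asm` and each non-ASM member's
#' score by `w_nonasm`; with weights (1, 1) this is the identity, which is
#' the unweighted mode.
#'
#' @param scores named numeric vector of member gene scores.
#' @param is_asm named logical vector labelling every member.
#' @param w a [pathway_weights()] object (or list with `w_asm`, `w_nonasm`).
#' @return named numeric vector of weighted scores.
#' @export
apply_weights <- function(scores, is_asm, w) {
  if (!all(names(scores) %in% names(is_asm)) || anyNA(is_asm[names(scores)])) {
    stop("every pathway gene must carry an ASM label", call. = FALSE)
  }
  lab <- is_asm[names(scores)]
  scores * ifelse(lab, w$w_asm, w$w_nonasm)
}

# ES for one pathway given the rank positions of its members in the
# genome-wide ordering. incr: weighted member scores in rank order.
# The running sum rises by incr/N_R at members and falls by dec between
# them; its maximum is attained immediately after a member step.
.es_from_positions <- function(pos, incr, N, dec = 1 / (N - length(pos))) {
  N_R <- sum(incr)
  if (N_R == 0) return(0)
  max(cumsum(incr) / N_R - (pos - seq_along(pos)) * dec)
}

#' GSEA-style enrichment score
#'
#' All `N` scored genes are ranked by score, descending (ties broken by
#' gene id for reproducibility). A running sum gains
#' `weighted_score / N_R` at each pathway member (`N_R` = sum of member
#' weighted scores) and loses `1/(N - N_H)` at each non-member; the ES is
#' the maximum of the running sum, a weighted Kolmogorov-Smirnov-like
#' statistic in (-1, 1]. `N_R = 0` is degenerate and yields ES = 0.
#'
#' @param members character vector of member gene ids (`1 <= N_H < N`).
#' @param all_scores named numeric vector of all gene scores (length `N`).
#' @param member_weighted_scores named numeric vector of the members'
#'   (possibly weighted) non-negative scores; defaults to their unweighted
#'   scores.
#' @return the enrichment score.
#' @export
enrichment_score <- function(members, all_scores,
                             member_weighted_scores = all_scores[members]) {
  N <- length(all_scores); N_H <- length(members)
  if (N_H < 1 || N_H >= N) stop("need 1 <= members < total genes", call. = FALSE)
  stopifnot(all(members %in% names(all_scores)))
  ord <- order(-all_scores, names(all_scores))
  rank_of <- stats::setNames(seq_len(N), names(all_scores)[ord])
  pos <- sort(rank_of[members])
  incr <- unname(member_weighted_scores[names(pos)])
  .es_from_positions(unname(pos), incr, N)
}

#' Sum-statistic and sum-square-statistic
#'
#' Self-contained set statistics: the sum, and the sum of squares, of the
#' (weighted) gene scores over the pathway members.
#'
#' @param member_weighted_scores numeric vector of member scores.
#' @return scalar statistic.
#' @export
sum_statistic <- function(member_weighted_scores) {
  stopifnot(length(member_weighted_scores) >= 1)
  sum(member_weighted_scores)
}

#' @rdname sum_statistic
#' @export
sum_square_statistic <- function(member_weighted_scores) {
  stopifnot(length(member_weighted_scores) >= 1)
  sum(member_weighted_scores^2)
}

# all six statistics for every pathway under one assignment of
# (score, informative) tuples to genes.  members/asm_members are lists of
# integer indices into the gene vector; asm flags stay attached to genes.
.pathway_stats_once <- function(score, informative, is_asm, gid_rank,
                                member_idx, weighted = TRUE) {
  N <- length(score)
  ord <- order(-score, gid_rank, method = "radix")
  rank_of <- integer(N); rank_of[ord] <- seq_len(N)
  P <- length(member_idx)
  out <- matrix(NA_real_, P, 6,
                dimnames = list(NULL, c("gsea_weighted", "gsea_unweighted",
                                        "sumst_weighted", "sumst_unweighted",
                                        "sumsq_weighted", "sumsq_unweighted")))
  for (j in seq_len(P)) {
    idx <- member_idx[[j]]
    a <- is_asm[idx]
    s <- score[idx]
    dec <- 1 / (N - length(idx))
    o <- order(rank_of[idx])
    pos <- rank_of[idx][o]
    out[j, "sumst_unweighted"] <- sum(s)
    out[j, "sumsq_unweighted"] <- sum(s^2)
    out[j, "gsea_unweighted"] <- .es_from_positions(pos, s[o], N, dec)
    if (weighted) {
      inf <- informative[idx]
      w <- .weight_pair(sum(a), sum(!a), sum(inf & a), sum(inf & !a))
      ws <- s * (a * w[1] + (!a) * w[2])
      out[j, "sumst_weighted"] <- sum(ws)
      out[j, "sumsq_weighted"] <- sum(ws^2)
      out[j, "gsea_weighted"] <- .es_from_positions(pos, ws[o], N, dec)
    }
  }
  out
}

#' Permutation empirical p-values for all pathways
#'
#' Each permutation jointly shuffles the per-gene `(gene_score,
#' is_informative)` tuples across all mapped genes while pathway
#' membership and per-gene ASM labels stay fixed; subset weights are
#' recomputed from the shuffled informative flags, so the weighting step
#' is part of the null. One permutation stream is shared by the three
#' methods and both modes. Empirical p-values use the add-one estimator
#' `(1 + #\{permuted >= observed\}) / (1 + B)`.
#'
#' @param gene_table data.frame from [score_genes()] (needs `gene_id`,
#'   `gene_score`, `is_informative`, `is_asm`).
#' @param pathways named list of gene-id vectors (size-filtered).
#' @param B number of permutations (default 5000, minimum 100).
#' @param seed RNG seed.
#' @param .perms optional list of explicit permutation index vectors
#'   (overrides `B` and `seed`; used by equivalence tests).
#' @return list with `observed` (P x 6 statistic matrix), `empirical_p`
#'   (same shape), and `weights` (data.frame of observed per-pathway
#'   weight fields).
#' @export
permutation_pvalues <- function(gene_table, pathways, B = 5000, seed = 1L,
                                .perms = NULL) {
  if (is.null(.perms) && B < 100) stop("B must be at least 100", call. = FALSE)
  gid <- gene_table$gene_id
  score <- gene_table$gene_score
  informative <- gene_table$is_informative
  is_asm <- gene_table$is_asm
  N <- length(gid)
  gid_rank <- match(gid, sort(gid))  # integer alphabetical rank for tie-breaks
  member_idx <- lapply(pathways, function(g) which(gid %in% g))
  bad <- vapply(member_idx, function(i) length(i) < 1L || length(i) >= N, TRUE)
  if (any(bad)) stop("pathway with no mapped genes or spanning all genes", call. = FALSE)

  obs <- .pathway_stats_once(score, informative, is_asm, gid_rank, member_idx)
  exceed <- matrix(0L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  if (is.null(.perms)) {
    set.seed(as.integer(seed))
    B <- as.integer(B)
    perms <- NULL
  } else {
    B <- length(.perms)
  }
  for (b in seq_len(B)) {
    pi <- if (is.null(.perms)) sample.int(N) else .perms[[b]]
    st <- .pathway_stats_once(score[pi], informative[pi], is_asm, gid_rank, member_idx)
    exceed <- exceed + (st >= obs)
  }
  weights <- do.call(rbind, lapply(seq_along(member_idx), function(j) {
    idx <- member_idx[[j]]
    a <- is_asm[idx]; inf <- informative[idx]
    w <- pathway_weights(sum(a), sum(!a), sum(inf & a), sum(inf & !a),
                         names(pathways)[j])
    data.frame(pathway = w$pathway_name, n = w$n, m = w$m, k_n = w$k_n,
               k_m = w$k_m, R_n = w$R_n, R_m = w$R_m, H = w$H,
               w_asm = w$w_asm, w_nonasm = w$w_nonasm, branch = w$rule_branch,
               stringsAsFactors = FALSE)
  }))
  list(observed = obs, empirical_p = (1 + exceed) / (1 + B), weights = weights)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort ascending, multiply `p_(i)` by `m/i`,
#' enforce monotonicity from the largest rank down, cap at 1, and return
#' the values in the input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Full pathway analysis
#'
#' Size-filters the pathways, runs the permutation machinery and applies
#' BH adjustment per method and mode, returning one row per pathway with
#' the observed weights and all statistic / p-value columns.
#'
#' @inheritParams permutation_pvalues
#' @param min_size,max_size mapped-size filter bounds (defaults 10, 380).
#' @param weighting `"both"` (default), `"on"` or `"off"`: which weighting
#'   modes to report.
#' @return data.frame with identity columns (`pathway`, `source`,
#'   `total_genes`, `genes_on_list`, `pct_asm_genes`), the weight fields,
#'   and `{method}_{mode}_{stat,p,bh}` columns.
#' @export
pathway_analysis <- function(gene_table, pathways, B = 5000, seed = 1L,
                             min_size = 10, max_size = 380,
                             weighting = c("both", "on", "off"),
                             .perms = NULL) {
  weighting <- match.arg(weighting)
  total <- vapply(pathways, length, 0L)
  src <- attr(pathways, "source")
  pw <- filter_pathways_by_size(pathways, gene_table$gene_id, min_size, max_size)
  if (!length(pw)) stop("no pathway passes the size filter", call. = FALSE)
  perm <- permutation_pvalues(gene_table, pw, B = B, seed = seed, .perms = .perms)

  asm_ids <- gene_table$gene_id[gene_table$is_asm]
  on_list <- vapply(pw, function(g) sum(g %in% gene_table$gene_id), 0L)
  n_asm <- vapply(pw, function(g) sum(g %in% asm_ids), 0L)
  out <- data.frame(pathway = names(pw),
                    source = if (is.null(src)) vapply(names(pw), .pathway_source, "")
                             else unname(src[names(pw)]),
                    total_genes = unname(total[names(pw)]),
                    genes_on_list = unname(on_list),
                    pct_asm_genes = round(100 * n_asm / on_list, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, perm$weights[, c("n", "m", "k_n", "k_m", "w_asm",
                                     "w_nonasm", "branch")])
  modes <- switch(weighting, both = c("weighted", "unweighted"),
                  on = "weighted", off = "unweighted")
  for (method in c("gsea", "sumst", "sumsq")) {
    for (mode in modes) {
      col <- paste(method, mode, sep = "_")
      out[[paste0(col, "_stat")]] <- perm$observed[, col]
      out[[paste0(col, "_p")]] <- perm$empirical_p[, col]
      out[[paste0(col, "_bh")]] <- bh_adjust(perm$empirical_p[, col])
    }
  }
  out
}

#' Select significant pathways
#'
#' A pathway is selected when any method-by-mode BH-adjusted p-value is
#' strictly below `fdr_threshold`; the triggering columns are recorded in
#' `triggered_by` (comma-separated), supporting per-method reporting.
#'
#' @param results data.frame from [pathway_analysis()].
#' @param fdr_threshold FDR significance threshold in (0,1), default 0.01.
#' @return the selected rows with an extra `triggered_by` column.
#' @export
significant_pathways <- function(results, fdr_threshold = 0.01) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  bh_cols <- grep("_bh$", names(results), value = TRUE)
  hit <- as.matrix(results[bh_cols]) < fdr_threshold
  sel <- rowSums(hit, na.rm = TRUE) > 0
  out <- results[sel, , drop = FALSE]
  out$triggered_by <- apply(hit[sel, , drop = FALSE], 1, function(h)
    paste(sub("_bh$", "", bh_cols[which(h)]), collapse = ","))
  rownames(out) <- NULL
  out
}
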