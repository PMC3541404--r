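# Follow-up on enriched pathways: GO-term over-representation of the genes
# they contain, and the over-represented-gene report.

#' GO-term over-representation of a query gene set
#'
#' One-sided hypergeometric upper-tail test per term: the probability of
#' observing at least the realized overlap between the query and the term,
#' drawing `|query|` genes from the universe. Terms are first restricted
#' to the universe (the mapped genes, not the whole genome, so the test is
#' reproducible without any external annotation service); terms disjoint
#' from the universe are skipped with a warning. No multiple-testing
#' correction is applied — the report is exploratory, filtered at raw
#' `p < p_cutoff` and truncated to the `top_k` smallest p-values.
#'
#' @param query_genes character vector of query gene ids (subset of the
#'   universe; non-empty).
#' @param go_sets named list of term gene-id vectors.
#' @param universe character vector of mapped gene ids.
#' @param top_k maximum number of reported terms (default 50).
#' @param p_cutoff raw p-value filter (default 0.05).
#' @return data.frame: `term_name`, `term_size`, `overlap`, `pct_overlap`
#'   (percent of term genes present in the query), `p_value`; sorted by
#'   p-value.
#' @export
go_overrepresentation <- function(query_genes, go_sets, universe,
                                  top_k = 50, p_cutoff = 0.05) {
  if (!length(query_genes)) stop("empty query gene set", call. = FALSE)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) stop("query must be a subset of the universe",
                                            call. = FALSE)
  Nu <- length(unique(universe))
  nq <- length(query_genes)
  rows <- lapply(names(go_sets), function(nm) {
    term <- intersect(go_sets[[nm]], universe)
    if (!length(term)) {
      warning(sprintf("term '%s' shares no genes with the universe; skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    ov <- length(intersect(term, query_genes))
    p <- stats::phyper(ov - 1, length(term), Nu - length(term), nq,
                       lower.tail = FALSE)
    data.frame(term_name = nm, term_size = length(term), overlap = ov,
               pct_overlap = round(100 * ov / length(term), 1), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term_name = character(0), term_size = integer(0),
                                      overlap = integer(0), pct_overlap = numeric(0),
                                      p_value = numeric(0)))
  out <- out[order(out$p_value, out$term_name), , drop = FALSE]
  out <- out[out$p_value < p_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Genes over-represented among the enriched pathways
#'
#' Selects genes that occur in strictly more than `fraction` of the
#' enriched pathways and have at least one SNP with p below `snp_alpha`
#' (judged on the gene's overall smallest SNP p-value, regardless of the
#' ASM min-p rule), and reports their SNP content.
#'
#' @param enriched_names names of the enriched pathways.
#' @param pathways named list of gene-id vectors (the tested collection).
#' @param gene_table data.frame from [score_genes()].
#' @param fraction membership fraction threshold in (0,1), default 0.2.
#' @param snp_alpha per-SNP significance threshold, default 0.05.
#' @return data.frame: `gene_id`, `set_label` (ASM / non-ASM),
#'   `n_pathways_containing`, `n_snps`, `pct_significant_snps`,
#'   `smallest_p`; ordered by gene id. Zero enriched pathways give an
#'   empty report.
#' @export
overrepresented_genes <- function(enriched_names, pathways, gene_table,
                                  fraction = 0.2, snp_alpha = 0.05) {
  stopifnot(fraction > 0, fraction < 1, snp_alpha > 0, snp_alpha < 1)
  empty <- data.frame(gene_id = character(0), set_label = character(0),
                      n_pathways_containing = integer(0), n_snps = integer(0),
                      pct_significant_snps = numeric(0), smallest_p = numeric(0))
  if (!length(enriched_names)) return(empty)
  K <- length(enriched_names)
  counts <- table(unlist(lapply(pathways[enriched_names], function(g)
    unique(intersect(g, gene_table$gene_id)))))
  sel <- names(counts)[counts > fraction * K]
  i <- match(sel, gene_table$gene_id)
  ok <- gene_table$min_p_all[i] < snp_alpha
  sel <- sel[ok]; i <- i[ok]
  if (!length(sel)) return(empty)
  out <- data.frame(gene_id = sel,
                    set_label = ifelse(gene_table$is_asm[i], "ASM", "non-ASM"),
                    n_pathways_containing = as.integer(counts[sel]),
                    n_snps = gene_table$n_snps[i],
                    pct_significant_snps = round(100 * gene_table$prop_significant[i], 1),
                    smallest_p = gene_table$min_p_all[i],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
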