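# Readers and writers for the external formats the pipeline touches:
# PLINK .assoc summary statistics, BED4 gene coordinates, the ASM SNP-CpG
# pair table, GMT gene sets, and the TSV results table.

#' Normalize chromosome labels to bare autosome integers
#'
#' Accepts `"chr1"` and `"1"` style labels; returns `NA` for anything that is
#' not an autosome in 1..22 (X/Y/MT are excluded throughout the package).
#'
#' @param x character or integer vector of chromosome labels.
#' @return integer vector with `NA` for non-autosomes.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(x))
  n[!is.na(n) & (n < 1L | n > 22L)] <- NA_integer_
  n
}

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Read PLINK `.assoc`-style association results
#'
#' Whitespace-delimited table with a header naming at least `CHR`, `SNP`,
#' `BP` and `P` (an optional `CHISQ` column is kept when present). Rows with
#' missing p-values and rows on non-autosomal chromosomes are dropped; the
#' counts are reported via [message()] and attached as attributes
#' `n_dropped_na` and `n_dropped_nonautosomal`.
#'
#' @param path path to the association file.
#' @return data.frame with columns `snp_id`, `chromosome` (integer 1..22),
#'   `position` (1-based bp), `p_value`, and `chi_square` if present.
#' @export
read_assoc <- function(path) {
  if (!file.exists(path)) .stop_fmt("association file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "nan"), colClasses = "character",
                          check.names = TRUE)
  for (col in c("CHR", "SNP", "BP", "P")) {
    if (!col %in% names(df)) .stop_fmt("missing mandatory column '%s' in %s", col, path)
  }
  raw_p <- df$P
  p <- suppressWarnings(as.numeric(raw_p))
  bad <- which(!is.na(raw_p) & is.na(p))
  if (length(bad)) {
    .stop_fmt("unparsable P value '%s' at line %d of %s",
              raw_p[bad[1]], bad[1] + 1L, path)  # +1 for the header line
  }
  pos <- suppressWarnings(as.integer(df$BP))
  if (anyNA(pos) && any(is.na(pos) & !is.na(df$BP))) {
    .stop_fmt("unparsable BP value at line %d of %s",
              which(is.na(pos) & !is.na(df$BP))[1] + 1L, path)
  }
  chrom <- normalize_chrom(df$CHR)

  drop_na <- is.na(p)
  keep <- !drop_na
  drop_chr <- !is.na(p) & is.na(chrom)
  keep <- keep & !is.na(chrom)
  out <- data.frame(snp_id = df$SNP[keep],
                    chromosome = chrom[keep],
                    position = pos[keep],
                    p_value = p[keep],
                    stringsAsFactors = FALSE)
  if ("CHISQ" %in% names(df)) {
    out$chi_square <- suppressWarnings(as.numeric(df$CHISQ[keep]))
  }
  if (any(out$p_value <= 0 | out$p_value > 1)) {
    .stop_fmt("p-value outside (0,1] at line %d of %s",
              which(p <= 0 | p > 1)[1] + 1L, path)
  }
  if (any(out$position < 1L)) .stop_fmt("position < 1 in %s", path)
  if (anyDuplicated(out$snp_id)) {
    .stop_fmt("duplicate SNP id '%s' in %s", out$snp_id[duplicated(out$snp_id)][1], path)
  }
  n_na <- sum(drop_na); n_chr <- sum(drop_chr)
  if (n_na) message(sprintf("read_assoc: dropped %d row(s) with missing P", n_na))
  if (n_chr) message(sprintf("read_assoc: dropped %d non-autosomal row(s)", n_chr))
  attr(out, "n_dropped_na") <- n_na
  attr(out, "n_dropped_nonautosomal") <- n_chr
  out
}

#' Read gene coordinates from a BED4 file
#'
#' External BED intervals are 0-based half-open; internally everything is
#' 1-based inclusive, so `start` becomes `start + 1` at ingestion and `end`
#' is kept. Duplicate gene ids and empty intervals are format errors;
#' non-autosomal genes are dropped with a logged count.
#'
#' @param path path to a BED4 file (chrom, start, end, name; no header).
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) .stop_fmt("gene table not found: %s", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"),
                          colClasses = c("character", "integer", "integer", "character"))
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1]
    .stop_fmt("empty or inverted BED interval for '%s' (start %d >= end %d)",
              df$gene_id[i], df$start[i], df$end[i])
  }
  if (anyDuplicated(df$gene_id)) {
    .stop_fmt("duplicate gene id '%s'", df$gene_id[duplicated(df$gene_id)][1])
  }
  chrom <- normalize_chrom(df$chrom)
  n_drop <- sum(is.na(chrom))
  if (n_drop) message(sprintf("read_gene_table: dropped %d non-autosomal gene(s)", n_drop))
  out <- data.frame(gene_id = df$gene_id[!is.na(chrom)],
                    chromosome = chrom[!is.na(chrom)],
                    start = df$start[!is.na(chrom)] + 1L,
                    end = df$end[!is.na(chrom)],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_nonautosomal") <- n_drop
  out
}

#' Read the ASM SNP-CpG pair table
#'
#' Tab-delimited with a header naming `snp_id`, `snp_chromosome`,
#' `snp_position`, `cpg_chromosome`, `cpg_position`, `target_gene_id`,
#' `mode` (`cis`/`trans`) and `p_value`. Cis pairs must lie on one
#' chromosome within 1 Mb (inclusive) of the CpG site; violations are
#' format errors. Pairs involving non-autosomal chromosomes are dropped
#' with a logged count (the analysis is restricted to autosomes).
#'
#' @param path path to the pair table.
#' @return data.frame of validated pairs, attribute `n_dropped_nonautosomal`.
#' @export
read_asm_pairs <- function(path) {
  if (!file.exists(path)) .stop_fmt("ASM pair table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("snp_id", "snp_chromosome", "snp_position", "cpg_chromosome",
            "cpg_position", "target_gene_id", "mode", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stop_fmt("missing column(s) %s in %s", paste(miss, collapse = ", "), path)
  if (!all(df$mode %in% c("cis", "trans"))) {
    .stop_fmt("invalid mode '%s' (must be cis or trans)",
              df$mode[!df$mode %in% c("cis", "trans")][1])
  }
  if (any(df$p_value <= 0 | df$p_value > 1)) .stop_fmt("ASM pair p-value outside (0,1]")
  snp_chr <- normalize_chrom(df$snp_chromosome)
  cpg_chr <- normalize_chrom(df$cpg_chromosome)
  drop <- is.na(snp_chr) | is.na(cpg_chr)
  n_drop <- sum(drop)
  if (n_drop) message(sprintf("read_asm_pairs: dropped %d non-autosomal pair(s)", n_drop))
  out <- data.frame(snp_id = df$snp_id, snp_chromosome = snp_chr,
                    snp_position = as.integer(df$snp_position),
                    cpg_chromosome = cpg_chr,
                    cpg_position = as.integer(df$cpg_position),
                    target_gene_id = df$target_gene_id,
                    mode = df$mode, p_value = df$p_value,
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  cis <- out$mode == "cis"
  viol <- cis & (out$snp_chromosome != out$cpg_chromosome |
                 abs(out$snp_position - out$cpg_position) > 1000000L)
  if (any(viol)) {
    i <- which(viol)[1]
    .stop_fmt("cis pair %s violates the 1 Mb same-chromosome rule", out$snp_id[i])
  }
  attr(out, "n_dropped_nonautosomal") <- n_drop
  out
}

#' Filter ASM pairs on their association p-values
#'
#' Retains cis pairs with `p_value < cis_alpha` and trans pairs with
#' `p_value < trans_alpha` (strict inequalities), preserving input order.
#' Idempotent, so it is safe on a table that was already filtered upstream.
#'
#' @param pairs data.frame as returned by [read_asm_pairs()].
#' @param cis_alpha,trans_alpha selection thresholds in (0,1); default 0.05.
#' @return the retained subset of `pairs`.
#' @export
filter_asm_pairs <- function(pairs, cis_alpha = 0.05, trans_alpha = 0.05) {
  stopifnot(cis_alpha > 0, cis_alpha < 1, trans_alpha > 0, trans_alpha < 1)
  keep <- (pairs$mode == "cis" & pairs$p_value < cis_alpha) |
          (pairs$mode == "trans" & pairs$p_value < trans_alpha)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.pathway_source <- function(name) {
  pre <- c(GO = "^GO_", KEGG = "^KEGG_", REACTOME = "^REACTOME_", BIOCARTA = "^BIOCARTA_")
  for (s in names(pre)) if (grepl(pre[[s]], name)) return(s)
  "literature"
}

#' Read gene sets from a GMT file
#'
#' One pathway per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate gene symbols within a line are deduplicated; a line with fewer
#' than three fields (i.e. no genes) is a format error, as is a duplicated
#' pathway name. The source database (GO/KEGG/Reactome/BioCarta/literature)
#' is inferred from the MSigDB-style name prefix.
#'
#' @param path path to the GMT file.
#' @return named list of character gene-id vectors, with attributes
#'   `description` and `source` (named character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short)) .stop_fmt("GMT line %d has fewer than 3 fields", short[1])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) .stop_fmt("duplicate pathway name '%s'", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  attr(sets, "source") <- stats::setNames(vapply(nm, .pathway_source, ""), nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (as from [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# format reals to 12 significant digits so write/read round-trips
.fmt_real <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], .fmt_real)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pathway results table
#'
#' Tab-delimited, one row per pathway: identity columns (`pathway`,
#' `source`, `total_genes`, `genes_on_list`, `pct_asm_genes`) followed by
#' `{method}_{mode}_{stat,p,bh}` for the three methods and the weighted /
#' unweighted modes present in `results`. Rows are ordered by the best
#' (smallest) BH-adjusted p-value across the statistic columns, ties broken
#' by pathway name; reals carry 12 significant digits.
#'
#' @param path output path.
#' @param results data.frame from [pathway_analysis()].
#' @return `path`, invisibly.
#' @export
write_results <- function(path, results) {
  if (is.null(results) || nrow(results) == 0L) .stop_fmt("no results to write")
  bh_cols <- grep("_bh$", names(results), value = TRUE)
  best <- do.call(pmin, c(unname(results[bh_cols]), list(na.rm = TRUE)))
  results <- results[order(best, results$pathway), , drop = FALSE]
  .write_tsv(results, path)
}

#' Read back a results table written by [write_results()]
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
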