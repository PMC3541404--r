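# End-to-end orchestration: ingest -> gene scoring -> weighting ->
# enrichment -> post-processing, with a manifest, structured logging and a
# command-line front end (verbs: simulate, run, annotate).

#' Build a run configuration
#'
#' Aggregates every tunable constant of the pipeline with its default:
#' 5 kb gene window, 0.05 significance thresholds, 10,000 gene-score
#' resamples, 5,000 pathway permutations, pathway sizes 10-380, FDR
#' threshold 0.01.
#'
#' @param assoc,genes,asm,gmt input file paths.
#' @param out output directory.
#' @param window_bp SNP-to-gene window in bp.
#' @param cis_alpha,trans_alpha ASM pair selection thresholds.
#' @param snp_alpha per-SNP significance threshold.
#' @param gene_stat `"adjusted"` or `"raw_chisq"`.
#' @param score_perms gene-score resampling replicates.
#' @param pathway_perms pathway permutations.
#' @param min_size,max_size pathway mapped-size filter.
#' @param fdr_threshold BH significance threshold.
#' @param weighting `"both"`, `"on"` or `"off"`.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(assoc, genes, asm, gmt, out,
                       window_bp = 5000, cis_alpha = 0.05, trans_alpha = 0.05,
                       snp_alpha = 0.05, gene_stat = "adjusted",
                       score_perms = 10000, pathway_perms = 5000,
                       min_size = 10, max_size = 380, fdr_threshold = 0.01,
                       weighting = "both", seed = 1L) {
  stopifnot(window_bp >= 0, cis_alpha > 0, cis_alpha < 1,
            trans_alpha > 0, trans_alpha < 1, snp_alpha > 0, snp_alpha < 1,
            score_perms >= 100, pathway_perms >= 100,
            min_size <= max_size, fdr_threshold > 0, fdr_threshold < 1,
            gene_stat %in% c("adjusted", "raw_chisq"),
            weighting %in% c("both", "on", "off"))
  structure(list(assoc = assoc, genes = genes, asm = asm, gmt = gmt, out = out,
                 window_bp = window_bp, cis_alpha = cis_alpha,
                 trans_alpha = trans_alpha, snp_alpha = snp_alpha,
                 gene_stat = gene_stat, score_perms = as.integer(score_perms),
                 pathway_perms = as.integer(pathway_perms),
                 min_size = as.integer(min_size), max_size = as.integer(max_size),
                 fdr_threshold = fdr_threshold, weighting = weighting,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `overrides`
#' (a named list, typically from command-line flags) wins over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stage order: ingest the four inputs, filter the ASM pairs, score genes,
#' run the weighted and unweighted pathway statistics with permutation
#' p-values and BH adjustment, then the follow-ups (GO over-representation
#' of genes in enriched non-GO pathways against the mapped-gene universe,
#' and the over-represented-gene report). Writes `gene_table.tsv`,
#' `weights.tsv`, `results.tsv`, `significant.tsv`, `go_results.tsv`,
#' `gene_report.tsv` and `manifest.json` under `config$out`. Identical
#' config and inputs give bit-identical outputs; on any stage failure the
#' partial outputs are removed and the stage is named in the error.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `gene_table`, `results`, `significant`,
#'   `go`, `gene_report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_files <- file.path(out_dir, c("gene_table.tsv", "weights.tsv", "results.tsv",
                                    "significant.tsv", "go_results.tsv",
                                    "gene_report.tsv", "manifest.json"))
  stage <- "ingest"
  res <- tryCatch({
    for (f in c(config$assoc, config$genes, config$asm)) {
      if (!file.exists(f)) .stop_fmt("input file not found: %s", f)
    }
    snps <- read_assoc(config$assoc)
    genes <- read_gene_table(config$genes)
    pairs_raw <- read_asm_pairs(config$asm)
    stage <- "enrichment-ingest"
    if (!file.exists(config$gmt)) .stop_fmt("GMT file not found: %s", config$gmt)
    pathways <- read_gmt(config$gmt)
    stage <- "asm-filter"
    pairs <- filter_asm_pairs(pairs_raw, config$cis_alpha, config$trans_alpha)
    .log_stage(stage, "%d of %d ASM pairs retained", nrow(pairs), nrow(pairs_raw))
    stage <- "gene-scoring"
    gene_table <- score_genes(snps, genes, pairs,
                              window_bp = config$window_bp,
                              snp_alpha = config$snp_alpha,
                              score_perms = config$score_perms,
                              seed = config$seed, gene_stat = config$gene_stat)
    .log_stage(stage, "%d genes mapped (%d ASM), genome-wide significant fraction %.4f",
               nrow(gene_table), sum(gene_table$is_asm),
               attr(gene_table, "genomewide_prop"))
    stage <- "enrichment"
    results <- pathway_analysis(gene_table, pathways, B = config$pathway_perms,
                                seed = config$seed + 1L,
                                min_size = config$min_size,
                                max_size = config$max_size,
                                weighting = config$weighting)
    sig <- significant_pathways(results, config$fdr_threshold)
    .log_stage(stage, "%d of %d pathways significant at FDR %g",
               nrow(sig), nrow(results), config$fdr_threshold)
    stage <- "postprocess"
    go_sets <- pathways[unname(attr(pathways, "source")[names(pathways)] == "GO")]
    nongo_sig <- sig$pathway[sig$source != "GO"]
    go_res <- if (length(nongo_sig) && length(go_sets)) {
      q <- intersect(unique(unlist(pathways[nongo_sig])), gene_table$gene_id)
      go_overrepresentation(q, go_sets, gene_table$gene_id)
    } else {
      data.frame(term_name = character(0), term_size = integer(0),
                 overlap = integer(0), pct_overlap = numeric(0),
                 p_value = numeric(0))
    }
    report <- overrepresented_genes(sig$pathway, pathways, gene_table,
                                    snp_alpha = config$snp_alpha)
    stage <- "write"
    .write_tsv(gene_table, out_files[1])
    .write_tsv(results[, c("pathway", "n", "m", "k_n", "k_m", "w_asm",
                           "w_nonasm", "branch")], out_files[2])
    write_results(out_files[3], results)
    .write_tsv(sig, out_files[4])
    .write_tsv(go_res, out_files[5])
    .write_tsv(report, out_files[6])
    manifest <- list(
      config = unclass(config),
      inputs = as.list(tools::md5sum(c(config$assoc, config$genes, config$asm,
                                       config$gmt))),
      counts = list(
        snps_read = nrow(snps),
        snps_dropped_na = attr(snps, "n_dropped_na"),
        snps_dropped_nonautosomal = attr(snps, "n_dropped_nonautosomal"),
        asm_pairs_read = nrow(pairs_raw), asm_pairs_retained = nrow(pairs),
        genes_mapped = nrow(gene_table),
        asm_genes = sum(gene_table$is_asm),
        nonasm_genes = sum(!gene_table$is_asm),
        genomewide_significant_prop = attr(gene_table, "genomewide_prop"),
        pathways_parsed = length(pathways),
        pathways_tested = nrow(results),
        pathways_significant = nrow(sig)))
    jsonlite::write_json(manifest, out_files[7], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(gene_table = gene_table, results = results, significant = sig,
         go = go_res, gene_report = report, manifest = manifest)
  }, error = function(e) {
    unlink(out_files)
    .stop_fmt("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# ---------------------------------------------------------------------------
# command-line interface: asmpath simulate|run|annotate

.cli_simulate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "asmpath simulate --config sim.yaml --out DIR [--seed S]",
    option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL)))
  opt <- optparse::parse_args(parser, args)
  if (is.null(opt$out)) { optparse::print_help(parser); return(1L) }
  cfg_args <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  if (!is.null(opt$seed)) cfg_args$seed <- opt$seed
  for (k in c("snps_per_gene", "gene_length_bp", "asm_snps_per_asm_gene",
              "pathway_size")) {
    if (!is.null(cfg_args[[k]])) cfg_args[[k]] <- unlist(cfg_args[[k]])
  }
  config <- do.call(synthetic_study_config, cfg_args)
  simulate_study(config, opt$out)
  message("synthetic study written to ", opt$out)
  0L
}

.cli_run <- function(args) {
  parser <- optparse::OptionParser(
    usage = "asmpath run --config run.yaml [--perms N --seed S --weighting on|off|both --out DIR]",
    option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--perms", type = "integer", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--weighting", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL)))
  opt <- optparse::parse_args(parser, args)
  if (is.null(opt$config)) { optparse::print_help(parser); return(1L) }
  overrides <- Filter(Negate(is.null),
                      list(pathway_perms = opt$perms, seed = opt$seed,
                           weighting = opt$weighting, out = opt$out))
  config <- read_run_config(opt$config, overrides)
  run_pipeline(config)
  0L
}

.cli_annotate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "asmpath annotate --genes query.txt --gmt go.gmt --universe genes.txt --out DIR",
    option_list = list(
      optparse::make_option("--genes", type = "character", default = NULL),
      optparse::make_option("--gmt", type = "character", default = NULL),
      optparse::make_option("--universe", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL)))
  opt <- optparse::parse_args(parser, args)
  if (any(vapply(opt[c("genes", "gmt", "universe", "out")], is.null, TRUE))) {
    optparse::print_help(parser); return(1L)
  }
  query <- readLines(opt$genes, warn = FALSE)
  universe <- readLines(opt$universe, warn = FALSE)
  go_sets <- read_gmt(opt$gmt)
  res <- go_overrepresentation(intersect(query, universe), go_sets, universe)
  if (!dir.exists(opt$out)) dir.create(opt$out, recursive = TRUE)
  .write_tsv(res, file.path(opt$out, "go_results.tsv"))
  0L
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `run` and `annotate` verbs; see
#' `inst/cli/asmpath` for the executable wrapper. Exit codes: 0 ok,
#' 1 usage error, 2 data/format error.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status.
#' @export
asmpath_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: asmpath <simulate|run|annotate> [options]")
    return(1L)
  }
  verb <- args[1]
  handler <- switch(verb, simulate = .cli_simulate, run = .cli_run,
                    annotate = .cli_annotate, NULL)
  if (is.null(handler)) {
    message("unknown verb '", verb, "'; expected simulate, run or annotate")
    return(1L)
  }
  tryCatch(handler(args[-1]), error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
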