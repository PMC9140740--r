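#' Default pipeline parameters
#' @return Named list of stage parameters with their defaults.
#' @export
default_params <- function() {
  list(permissive_evalue = 1.0,
       strict_evalue = 1e-4,
       window = 250000,
       anchor = "interval",
       paralog_evalue = 1e-10,
       top_n_hits = 5,
       min_block_size = 5,
       max_gap = 25,
       proximal_max_rank_gap = 20,
       min_support = 50,
       ingroup = c("Ef", "Nc", "Nt"),
       species_tree = DEFAULT_SPECIES_TREE,
       low_threshold = 1.0,
       expansion_min_size = 10)
}

#' Load a pipeline configuration from YAML
#'
#' The file has two blocks: `inputs` (paths to `gff`, `hmm_hits`,
#' `blast_hits`, `rescan_hits`, `domain_hits`, and optionally
#' `subclass_hints`, `allvall`, `chromosomes`, `tree`, `tree_subclasses`,
#' `expr`) and `params` (any of [default_params()]). Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return Config list suitable for [run_pipeline()].
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$inputs <- lapply(cfg$inputs, function(p)
    if (file.exists(p)) p else file.path(base, p))
  cfg
}

#' Run the full survey pipeline
#'
#' Executes identification, architecture classification, cluster calling,
#' duplication typing, lineage counting and expression profiling in
#' order, cross-checks the internal sums, and returns a `SurveyReport`
#' list. Stages whose inputs are absent are marked `skipped`.
#'
#' @param config List with `inputs` (named file paths; see
#'   [load_pipeline_config()]) and optional `params` overriding
#'   [default_params()].
#' @param out_dir Optional directory for stage TSVs plus `report.json`
#'   and `report.md`.
#' @return A `SurveyReport` list with components `totals`,
#'   `architecture_groups`, `locus_summary`, `loci`, `duplication`,
#'   `lineage`, `expression`, `calls`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  inp <- config$inputs
  par <- utils::modifyList(default_params(), config$params %||% list())
  need <- c("gff", "hmm_hits", "blast_hits", "rescan_hits", "domain_hits")
  miss <- setdiff(need, names(inp))
  if (length(miss))
    nbs_stop(paste("missing required inputs:", paste(miss, collapse = ", ")),
             "nbsurvey_config_error")

  genes <- read_gff(inp[["gff"]])
  hmm <- read_hit_table(inp[["hmm_hits"]], "hmm_tab")
  bls <- read_hit_table(inp[["blast_hits"]], "blast_tab12")
  rescan <- read_hit_table(inp[["rescan_hits"]], "hmm_tab")
  dom <- read_hit_table(inp[["domain_hits"]], "hmm_tab")

  candidates <- merge_candidates(hmm, bls, evalue_max = par$permissive_evalue)
  nbs_ids <- strict_rescan_filter(candidates, rescan,
                                  threshold = par$strict_evalue)
  hints <- NULL
  if (!is.null(inp[["subclass_hints"]]) && file.exists(inp[["subclass_hints"]])) {
    h <- read.delim(inp[["subclass_hints"]], stringsAsFactors = FALSE)
    hints <- setNames(h$subclass, h$gene_id)
  }
  annots <- build_domain_annotations(dom)
  calls <- classify_architectures(annots, intersect(nbs_ids, names(annots)),
                                  hints = hints)
  arch_groups <- summarize_architecture_groups(calls)

  chromosomes <- NULL
  if (!is.null(inp[["chromosomes"]]) && file.exists(inp[["chromosomes"]]))
    chromosomes <- read.delim(inp[["chromosomes"]], stringsAsFactors = FALSE)
  nbs_genes <- genes[genes$gene_id %in% nbs_ids, , drop = FALSE]
  assignment <- call_clusters(nbs_genes, window = par$window,
                              anchor = par$anchor)
  locus_summary <- distribution_summary(assignment, chromosomes)
  length_cor <- if (!is.null(chromosomes) && nrow(chromosomes) >= 3L)
    length_correlation(locus_summary$per_chromosome,
                       chromosomes[c("chrom", "length")])
  else NULL

  duplication <- list(skipped = TRUE)
  if (!is.null(inp[["allvall"]]) && file.exists(inp[["allvall"]])) {
    sim <- read_hit_table(inp[["allvall"]], "blast_tab12")
    pairs <- find_paralog_pairs(sim, evalue_max = par$paralog_evalue,
                                top_n_hits = par$top_n_hits)
    blocks <- detect_collinear_blocks(pairs, genes,
                                      min_block_size = par$min_block_size,
                                      max_gap = par$max_gap)
    labels <- classify_duplications(nbs_genes, pairs, blocks,
                                    proximal_max_rank_gap = par$proximal_max_rank_gap)
    duplication <- list(skipped = FALSE, pairs = pairs, blocks = blocks,
                        labels = labels,
                        summary = summarize_duplications(labels))
  }

  lineage <- list(skipped = TRUE)
  if (!is.null(inp[["tree"]]) && file.exists(inp[["tree"]])) {
    stree <- read_tree(inp[["tree"]])
    stree <- collapse_low_support(stree, min_support = par$min_support)
    rec <- reconcile(stree, par$ingroup)
    subclass_map <- NULL
    if (!is.null(inp[["tree_subclasses"]]) && file.exists(inp[["tree_subclasses"]])) {
      ts <- read.delim(inp[["tree_subclasses"]], stringsAsFactors = FALSE)
      subclass_map <- setNames(ts$subclass, ts$gene_id)
    }
    rep_lin <- count_ancestral_lineages(rec, species_tree = par$species_tree,
                                        subclass_map = subclass_map)
    lineage <- list(skipped = FALSE, report = rep_lin,
                    expansions = detect_expansions(rep_lin,
                                                   min_size = par$expansion_min_size))
  }

  expression <- list(skipped = TRUE)
  if (!is.null(inp[["expr"]]) && file.exists(inp[["expr"]])) {
    mat <- read_expression(inp[["expr"]])
    expression <- c(list(skipped = FALSE),
                    classify_expression(mat, nbs_ids,
                                        low_threshold = par$low_threshold))
  }

  totals <- list(
    annotated_genes = nrow(genes),
    candidates = length(candidates),
    nbs_genes = length(nbs_ids),
    nbs_fraction_percent = 100 * length(nbs_ids) / max(1L, nrow(genes)),
    per_subclass = as.list(table(calls$subclass)))
  report <- list(totals = totals,
                 architecture_groups = arch_groups,
                 calls = calls,
                 locus_summary = locus_summary,
                 loci = assignment,
                 length_correlation = length_cor,
                 duplication = duplication,
                 lineage = lineage,
                 expression = expression,
                 provenance = list(inputs = inp, params = par,
                                   version = as.character(utils::packageVersion("nbsurvey"))))
  check_report(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Cross-check the report's internal sums; inconsistency is a bug upstream
# and must fail loudly.
check_report <- function(report) {
  t <- report$totals
  if (sum(unlist(t$per_subclass)) != nrow(report$calls))
    nbs_stop("subclass counts do not sum to classified genes",
             "nbsurvey_report_error")
  ls <- report$locus_summary$totals
  if (ls$loci != ls$clusters + ls$singletons ||
      ls$genes != ls$clustered_genes + ls$singletons)
    nbs_stop("locus totals inconsistent", "nbsurvey_report_error")
  if (!report$duplication$skipped &&
      sum(report$duplication$summary$count) != nrow(report$duplication$labels))
    nbs_stop("duplication labels do not partition the gene set",
             "nbsurvey_report_error")
  invisible(report)
}

#' Render display percentages for a report
#'
#' Percentages are reported at the conventional display precision:
#' whole percents for duplication-type shares and the genome fraction,
#' one decimal for architecture-group shares within a subclass. Zero
#' denominators render as `"N/A"`.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (0 or 1).
#' @return Character scalar like `"21%"` or `"33.3%"`.
#' @export
format_percent <- function(numerator, denominator, digits = 0) {
  if (is.na(denominator) || denominator == 0) return("N/A")
  sprintf(paste0("%.", digits, "f%%"), round(100 * numerator / denominator,
                                             digits))
}

#' Summary percentage fields of a survey report
#'
#' @param report A `SurveyReport` from [run_pipeline()].
#' @return Named list of display strings plus their full-precision values.
#' @export
summarize_percentages <- function(report) {
  ls <- report$locus_summary$totals
  out <- list(
    nbs_fraction = format_percent(report$totals$nbs_genes,
                                  report$totals$annotated_genes, 1),
    percent_clustered = format_percent(ls$clustered_genes, ls$genes),
    mean_cluster_size = if (is.na(ls$mean_cluster_size)) "N/A"
    else as.character(round(ls$mean_cluster_size)),
    mean_cluster_size_value = ls$mean_cluster_size)
  if (!report$duplication$skipped) {
    s <- report$duplication$summary
    n <- sum(s$count)
    for (i in seq_len(nrow(s)))
      out[[paste0("share_", s$label[i])]] <- format_percent(s$count[i], n)
  }
  out
}

#' Write a survey report to disk
#'
#' Emits the stage tables as TSV plus `report.json` (full precision) and
#' a compact human-readable `report.md`. Regeneration from identical
#' inputs is byte-identical.
#'
#' @param report A `SurveyReport`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  w(report$calls, "calls.tsv")
  w(report$architecture_groups, "architecture_groups.tsv")
  w(report$loci$loci, "loci.tsv")
  if (!report$duplication$skipped) {
    w(report$duplication$labels, "duplication_labels.tsv")
    w(report$duplication$blocks, "collinear_blocks.tsv")
  }
  if (!report$lineage$skipped)
    w(report$lineage$report$lineages, "lineages.tsv")
  if (!report$expression$skipped)
    w(report$expression$calls, "expression_calls.tsv")
  json <- list(totals = report$totals,
               locus_totals = report$locus_summary$totals,
               per_chromosome = report$locus_summary$per_chromosome,
               length_correlation = report$length_correlation,
               duplication_summary = if (!report$duplication$skipped)
                 report$duplication$summary else "skipped",
               lineage_total = if (!report$lineage$skipped)
                 report$lineage$report$total else "skipped",
               lineage_inherited = if (!report$lineage$skipped)
                 as.list(report$lineage$report$inherited) else "skipped",
               fraction_low = if (!report$expression$skipped)
                 report$expression$fraction_low else "skipped",
               percent_display = summarize_percentages(report))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c("# NBS-LRR survey report", "",
          sprintf("- Annotated genes: %d", report$totals$annotated_genes),
          sprintf("- NBS-LRR genes: %d (%s of annotated genes)",
                  report$totals$nbs_genes,
                  format_percent(report$totals$nbs_genes,
                                 report$totals$annotated_genes, 1)),
          sprintf("- Subclasses: %s",
                  paste(sprintf("%s=%d", names(report$totals$per_subclass),
                                unlist(report$totals$per_subclass)),
                        collapse = ", ")),
          sprintf("- Loci: %d (%d singletons + %d clusters; %d clustered genes)",
                  report$locus_summary$totals$loci,
                  report$locus_summary$totals$singletons,
                  report$locus_summary$totals$clusters,
                  report$locus_summary$totals$clustered_genes))
  if (!report$duplication$skipped) {
    s <- report$duplication$summary
    md <- c(md, sprintf("- Duplication types: %s",
                        paste(sprintf("%s=%d", s$label, s$count),
                              collapse = ", ")))
  }
  if (!report$lineage$skipped)
    md <- c(md, sprintf("- Ancestral lineages: %d",
                        report$lineage$report$total))
  if (!report$expression$skipped)
    md <- c(md, sprintf("- Fraction lowly expressed: %.3f",
                        report$expression$fraction_low))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
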