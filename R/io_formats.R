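#' @importFrom stats cor.test p.adjust rexp rgamma runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Internal: stop with a classed condition so callers/tests can distinguish
# validation problems from parse problems.
nbs_stop <- function(msg, class) {
  stop(structure(class = c(class, "nbsurvey_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read gene models from a GFF3 annotation
#'
#' Parses the `gene` features of a GFF3 file into a gene-model table, the
#' positional backbone used by cluster calling and duplication typing.
#' Coordinates are kept 1-based inclusive as in the file. A per-chromosome
#' `rank` (0-based ordinal in start order, ties broken by end then gene id)
#' is computed, which is the gene-order coordinate that tandem/proximal
#' classification and collinearity chaining operate on.
#'
#' @param path Path to a GFF3 file. Features with type `gene` must carry an
#'   `ID` attribute.
#' @param feature_type Feature type to extract (default `"gene"`).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tgene\t900\t950\t.\t-\t.\tID=g3",
#'   "chr1\tsrc\tgene\t5000\t5100\t.\t+\t.\tID=g2"), gff)
#' read_gff(gff)
#' @export
read_gff <- function(path, feature_type = "gene") {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      nbs_stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                       i, nf), "nbsurvey_parse_error")
  }
  if (length(body) == 0L) return(empty_gene_models())
  df <- as.data.frame(rtracklayer::readGFF(path,
                                           filter = list(type = feature_type)))
  if (nrow(df) == 0L) return(empty_gene_models())
  ids <- as.character(df$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    nbs_stop("gene feature without an ID attribute", "nbsurvey_validation_error")
  if (anyDuplicated(ids))
    nbs_stop(sprintf("duplicate gene ID(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "nbsurvey_validation_error")
  gm <- data.frame(gene_id = ids,
                   chrom = as.character(df$seqid),
                   start = as.integer(df$start),
                   end = as.integer(df$end),
                   strand = as.character(df$strand),
                   stringsAsFactors = FALSE)
  gm$strand[!gm$strand %in% c("+", "-")] <- "+"
  as_gene_models(gm)
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), chrom = character(),
             start = integer(), end = integer(),
             strand = character(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' Attach per-chromosome gene-order ranks to a gene table
#'
#' Ranks are 0-based ordinals in ascending start order within each
#' chromosome; ties are broken by end coordinate and then gene id so the
#' ordering is deterministic.
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'   and optionally `strand`.
#' @return The same table, sorted by chromosome and start, with a `rank`
#'   column.
#' @export
as_gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) == 0L) return(empty_gene_models())
  if (anyDuplicated(genes$gene_id))
    nbs_stop("gene ids must be unique genome-wide", "nbsurvey_validation_error")
  if (any(genes$start < 1L) || any(genes$end < genes$start))
    nbs_stop("gene intervals must satisfy 1 <= start <= end",
             "nbsurvey_validation_error")
  if (is.null(genes$strand)) genes$strand <- "+"
  o <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chrom,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes[c("gene_id", "chrom", "start", "end", "strand", "rank")]
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model table as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "nbsurvey"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a homology hit table
#'
#' Supports the two tabular dialects the pipeline consumes: HMMER
#' `--tblout`-style space/tab tables (`hmm_tab`: target, query, E-value,
#' score, optional envelope coordinates) and 12-column BLAST `outfmt 6`
#' (`blast_tab12`). Comment lines (`#`) are skipped; E-values in
#' scientific notation are parsed.
#'
#' The `hmm_tab` dialect used throughout this package is a 7-column table:
#' `query_id target evalue score q_start q_end source`; the same layout
#' carries NB-ARC re-scan hits and CDD-style per-residue domain segments.
#'
#' @param path Path to the table.
#' @param dialect `"hmm_tab"` or `"blast_tab12"`.
#' @return A `data.frame` with columns `query_id`, `target`, `evalue`,
#'   `score`, `q_start`, `q_end`, `source`.
#' @export
read_hit_table <- function(path, dialect = c("hmm_tab", "blast_tab12")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (dialect == "blast_tab12") 12L else 7L
  if (any(nf != want))
    nbs_stop(sprintf("%s dialect expects %d columns, found rows with %s columns",
                     dialect, want, paste(unique(nf[nf != want]), collapse = "/")),
             "nbsurvey_dialect_error")
  m <- do.call(rbind, fields)
  if (dialect == "blast_tab12") {
    hits <- data.frame(query_id = m[, 1], target = m[, 2],
                       evalue = as.numeric(m[, 11]), score = as.numeric(m[, 12]),
                       q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                       source = "blast", stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(query_id = m[, 1], target = m[, 2],
                       evalue = as.numeric(m[, 3]), score = as.numeric(m[, 4]),
                       q_start = as.integer(m[, 5]), q_end = as.integer(m[, 6]),
                       source = m[, 7], stringsAsFactors = FALSE)
  }
  if (anyNA(hits$evalue))
    nbs_stop("unparseable E-value field", "nbsurvey_parse_error")
  if (any(hits$evalue < 0))
    nbs_stop("negative E-value", "nbsurvey_validation_error")
  bad <- !is.na(hits$q_start) & !is.na(hits$q_end) & hits$q_start > hits$q_end
  if (any(bad))
    nbs_stop("hit with q_start > q_end", "nbsurvey_validation_error")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), target = character(),
             evalue = numeric(), score = numeric(),
             q_start = integer(), q_end = integer(),
             source = character(), stringsAsFactors = FALSE)
}

#' Write a hit table in the package's 7-column hmm_tab dialect
#' @param hits Hit table (`query_id`, `target`, `evalue`, `score`,
#'   `q_start`, `q_end`, `source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits[c("query_id", "target", "evalue", "score",
                     "q_start", "q_end", "source")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted gene tree with species-tagged tips
#'
#' Reads a newick tree via \pkg{ape} and maps every tip to a species with a
#' configurable rule; the default takes the tip-label prefix before the
#' first underscore (`"Ef_g123"` belongs to species `"Ef"`). Internal-node
#' support values (newick node labels) are retained as numbers where they
#' parse.
#'
#' @param path Path to a newick file.
#' @param species_delim Delimiter separating the species tag from the rest
#'   of the tip label (default `"_"`).
#' @return A list with elements `tree` (an `ape::phylo`), `species` (named
#'   character vector tip label -> species) and `support` (numeric vector,
#'   one per internal node, `NA` where absent).
#' @export
read_tree <- function(path, species_delim = "_") {
  tree <- ape::read.tree(path)
  if (is.null(tree)) nbs_stop("could not parse newick file", "nbsurvey_parse_error")
  if (!ape::is.rooted(tree) && ape::Ntip(tree) > 2L)
    nbs_stop("tree is unrooted (basal trifurcation); root it with an outgroup first",
             "nbsurvey_rooting_error")
  species_tree_labels(tree, species_delim)
}

species_tree_labels <- function(tree, species_delim = "_") {
  labs <- tree$tip.label
  has_delim <- grepl(species_delim, labs, fixed = TRUE)
  if (any(!has_delim))
    nbs_stop(sprintf("tip label(s) without species tag ('<sp>%s...'): %s",
                     species_delim, paste(labs[!has_delim], collapse = ", ")),
             "nbsurvey_labeling_error")
  species <- vapply(strsplit(labs, species_delim, fixed = TRUE),
                    `[[`, character(1), 1L)
  names(species) <- labs
  support <- if (is.null(tree$node.label)) {
    rep(NA_real_, max(tree$Nnode, 0L))
  } else {
    suppressWarnings(as.numeric(tree$node.label))
  }
  list(tree = tree, species = species, support = support)
}

#' Write a species-tagged tree to newick
#' @param stree List as returned by [read_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(stree, path) {
  tree <- stree$tree
  if (!is.null(stree$support) && any(!is.na(stree$support))) {
    lab <- ifelse(is.na(stree$support), "",
                  format(stree$support, trim = TRUE, scientific = FALSE))
    tree$node.label <- lab
  }
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First row = sample names, first column = gene ids, values are
#' non-negative abundances (TPM or equivalent).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rownames = genes, colnames = samples.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    nbs_stop("duplicate gene ids in expression matrix", "nbsurvey_validation_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE))
    nbs_stop("negative abundance value", "nbsurvey_validation_error")
  m
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix (genes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
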