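#' Call NBS-LRR gene clusters with a flanking-window rule
#'
#' Two family members are placed in the same cluster when one lies within a
#' fixed window (default 250 kb) upstream or downstream of the other on
#' the same chromosome, i.e. when the inter-gene gap is at most `window`
#' bases; the relation is chained transitively (single linkage), so a
#' locus is a connected component under the pairwise rule. Loci with a
#' single member are singletons. Implemented as a sorted sweep per
#' chromosome: genes are taken in start order and a new locus opens
#' whenever the next start exceeds the running maximum end by more than
#' the window.
#'
#' With `anchor = "start"` the distance is measured between gene start
#' points instead of between full intervals.
#'
#' @param genes Gene-model table restricted to confirmed NBS genes.
#' @param window Flanking-window size in bases (default 250000).
#' @param anchor `"interval"` (default; linkage when gap between gene
#'   intervals <= window) or `"start"` (linkage when start-point distance
#'   <= window).
#' @return A list with `loci` (data.frame `locus_id`, `chrom`, `kind`,
#'   `n_genes`, `span_start`, `span_end`, `members`) and `membership`
#'   (named vector gene id -> locus id).
#' @export
call_clusters <- function(genes, window = 250000, anchor = c("interval", "start")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 0)
  if (nrow(genes) == 0L)
    return(list(loci = data.frame(locus_id = character(), chrom = character(),
                                  kind = character(), n_genes = integer(),
                                  span_start = integer(), span_end = integer(),
                                  members = character(),
                                  stringsAsFactors = FALSE),
                membership = setNames(character(0), character(0))))
  loci <- list()
  membership <- character(0)
  for (chrom in sort(unique(genes$chrom))) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    comp <- integer(nrow(g))
    comp[1] <- 1L
    run_max_end <- g$end[1]
    run_max_start <- g$start[1]
    for (i in seq_len(nrow(g))[-1]) {
      linked <- if (anchor == "interval") {
        # gap between [.,run_max_end] and [start_i,.]; overlap counts
        g$start[i] - run_max_end <= window
      } else {
        g$start[i] - run_max_start <= window
      }
      comp[i] <- if (linked) comp[i - 1L] else comp[i - 1L] + 1L
      run_max_end <- if (linked) max(run_max_end, g$end[i]) else g$end[i]
      run_max_start <- if (linked) max(run_max_start, g$start[i]) else g$start[i]
    }
    for (k in unique(comp)) {
      members <- g$gene_id[comp == k]
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = chrom,
        kind = if (length(members) >= 2L) "cluster" else "singleton",
        n_genes = length(members),
        span_start = min(g$start[comp == k]),
        span_end = max(g$end[comp == k]),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
      membership[members] <- length(loci)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$span_start), , drop = FALSE]
  out$locus_id <- sprintf("L%03d", seq_len(nrow(out)))
  # remap membership to the reordered locus ids
  old_order <- as.integer(rownames(out))
  map <- setNames(out$locus_id, old_order)
  membership <- setNames(map[as.character(membership)], names(membership))
  rownames(out) <- NULL
  list(loci = out[c("locus_id", "chrom", "kind", "n_genes",
                    "span_start", "span_end", "members")],
       membership = membership)
}

#' Summarize the chromosomal distribution of NBS loci
#'
#' Per-chromosome gene and locus counts plus family-level totals:
#' number of genes, loci, singletons, clusters, clustered genes,
#' mean/max cluster size and percent of genes in clusters. Chromosomes
#' with no family member are reported with count zero.
#'
#' @param assignment Output of [call_clusters()].
#' @param chromosomes Optional `data.frame` with `chrom` and `length`
#'   covering all chromosomes (so empty ones are reported).
#' @return List with `per_chromosome` (data.frame) and `totals` (list).
#' @export
distribution_summary <- function(assignment, chromosomes = NULL) {
  loci <- assignment$loci
  chroms <- if (!is.null(chromosomes)) as.character(chromosomes$chrom)
  else sort(unique(loci$chrom))
  per <- data.frame(chrom = chroms, stringsAsFactors = FALSE)
  per$n_genes <- vapply(chroms, function(c)
    sum(loci$n_genes[loci$chrom == c]), integer(1))
  per$n_loci <- vapply(chroms, function(c)
    sum(loci$chrom == c), integer(1))
  if (!is.null(chromosomes)) per$length <- chromosomes$length
  clusters <- loci[loci$kind == "cluster", , drop = FALSE]
  n_genes <- sum(loci$n_genes)
  n_clustered <- sum(clusters$n_genes)
  totals <- list(
    genes = n_genes,
    loci = nrow(loci),
    singletons = sum(loci$kind == "singleton"),
    clusters = nrow(clusters),
    clustered_genes = n_clustered,
    mean_cluster_size = if (nrow(clusters)) n_clustered / nrow(clusters) else NA_real_,
    max_cluster_size = if (nrow(clusters)) max(clusters$n_genes) else 0L,
    percent_clustered = if (n_genes) 100 * n_clustered / n_genes else NA_real_)
  stopifnot(totals$genes == totals$clustered_genes + totals$singletons,
            totals$loci == totals$clusters + totals$singletons)
  list(per_chromosome = per, totals = totals)
}

#' Rank correlation between family size and chromosome length
#'
#' Spearman rank correlation (midranks on ties) of per-chromosome family
#' counts against chromosome lengths, used to ask whether larger
#' chromosomes simply carry more family members.
#'
#' @param per_chrom_counts `data.frame` with `chrom` and `n_genes`.
#' @param chrom_lengths `data.frame` with `chrom` and `length`.
#' @return List with `rho`, `p_value` and `degenerate` (TRUE when one of
#'   the variables has zero variance, in which case `rho` is reported
#'   as 0).
#' @export
length_correlation <- function(per_chrom_counts, chrom_lengths) {
  m <- merge(per_chrom_counts[c("chrom", "n_genes")],
             chrom_lengths[c("chrom", "length")], by = "chrom")
  if (nrow(m) < 3L)
    nbs_stop("need at least 3 chromosomes for a rank correlation",
             "nbsurvey_insufficient_data_error")
  if (length(unique(m$n_genes)) == 1L || length(unique(m$length)) == 1L)
    return(list(rho = 0, p_value = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(cor.test(m$n_genes, m$length, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, degenerate = FALSE)
}
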