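#' Derive paralog pairs from an all-vs-all protein similarity table
#'
#' Self-hits are removed, each query keeps at most its `top_n_hits` best
#' non-self subjects by bitscore at `evalue_max` or below, and surviving
#' hits are deduplicated into unordered pairs.
#'
#' @param similarity Hit table from an all-against-all BLASTp
#'   (`query_id`, `target`, `evalue`, `score`).
#' @param evalue_max E-value ceiling (default `1e-10`).
#' @param top_n_hits Best non-self subjects kept per query (default 5).
#' @return `data.frame` with `gene_a`, `gene_b` (lexicographic order,
#'   unique rows), `evalue`, `bitscore`.
#' @export
find_paralog_pairs <- function(similarity, evalue_max = 1e-10, top_n_hits = 5) {
  h <- similarity[similarity$query_id != similarity$target &
                    similarity$evalue <= evalue_max, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  h <- h[order(h$query_id, -h$score, h$evalue), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$query_id), function(i) {
    tgt <- h$target[i]
    i[!duplicated(tgt)][seq_len(min(top_n_hits, length(unique(tgt))))]
  }), use.names = FALSE)
  h <- h[sort(keep), , drop = FALSE]
  a <- pmin(h$query_id, h$target)
  b <- pmax(h$query_id, h$target)
  key <- paste(a, b, sep = "\r")
  o <- order(key, h$evalue)
  first <- !duplicated(key[o])
  out <- data.frame(gene_a = a[o][first], gene_b = b[o][first],
                    evalue = h$evalue[o][first], bitscore = h$score[o][first],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# Best chain over anchors in one orientation by dynamic programming.
# x, y: rank coordinates; chain requires strictly increasing x with
# 0 < dx <= max_gap and, for orientation +1, strictly increasing y with
# 0 < dy <= max_gap (orientation -1: strictly decreasing, |dy| <= max_gap).
# Returns indices of one maximum-cardinality chain (ties broken towards
# the lexicographically smallest index sequence).
best_chain_dp <- function(x, y, max_gap, orientation = 1L) {
  n <- length(x)
  o <- order(x, orientation * y)
  x <- x[o]; y <- y[o]
  best <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      dx <- x[j] - x[i]
      dy <- orientation * (y[j] - y[i])
      if (dx > 0L && dx <= max_gap && dy > 0L && dy <= max_gap &&
          best[i] + 1L > best[j]) {
        best[j] <- best[i] + 1L
        prev[j] <- i
      }
    }
  }
  jstar <- which.max(best)
  chain <- integer(0)
  while (!is.na(jstar)) {
    chain <- c(jstar, chain)
    jstar <- prev[jstar]
  }
  o[chain]
}

#' Detect collinear (syntenic) blocks by anchor chaining
#'
#' Paralog pairs between positioned genes are converted to anchors in
#' gene-rank coordinates per (unordered) chromosome pair, and chained by
#' dynamic programming maximizing anchor count under a rank-gap ceiling on
#' both axes; both parallel and antiparallel diagonals are searched.
#' Chains are extracted greedily (best chain first, its anchors removed,
#' repeat) and reported when they reach `min_block_size` anchors. A gene
#' may appear in several blocks.
#'
#' @param pairs Paralog pairs from [find_paralog_pairs()].
#' @param genes Gene-model table covering *all* genes (the background gene
#'   order defines ranks).
#' @param min_block_size Minimum anchors per reported block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors on either
#'   axis (default 25).
#' @return `data.frame` of anchors with `block_id`, `chrom_a`, `chrom_b`,
#'   `gene_a`, `gene_b`, `rank_a`, `rank_b`, `n_anchors`, `orientation`.
#' @export
detect_collinear_blocks <- function(pairs, genes, min_block_size = 5,
                                    max_gap = 25) {
  empty <- data.frame(block_id = character(), chrom_a = character(),
                      chrom_b = character(), gene_a = character(),
                      gene_b = character(), rank_a = integer(),
                      rank_b = integer(), n_anchors = integer(),
                      orientation = integer(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  idx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes$gene_id)
  if (length(miss))
    nbs_stop(sprintf("paralog pair references unpositioned gene(s): %s",
                     paste(head(miss, 5), collapse = ", ")),
             "nbsurvey_validation_error")
  ca <- genes$chrom[idx[pairs$gene_a]]
  cb <- genes$chrom[idx[pairs$gene_b]]
  ra <- genes$rank[idx[pairs$gene_a]]
  rb <- genes$rank[idx[pairs$gene_b]]
  # orient each anchor so chrom_a <= chrom_b (rank_a on chrom_a axis)
  flip <- ca > cb
  anch <- data.frame(
    chrom_a = ifelse(flip, cb, ca), chrom_b = ifelse(flip, ca, cb),
    gene_a = ifelse(flip, pairs$gene_b, pairs$gene_a),
    gene_b = ifelse(flip, pairs$gene_a, pairs$gene_b),
    rank_a = ifelse(flip, rb, ra), rank_b = ifelse(flip, ra, rb),
    stringsAsFactors = FALSE)
  blocks <- list()
  for (cp in split(anch, paste(anch$chrom_a, anch$chrom_b, sep = "\r"))) {
    pool <- cp
    repeat {
      if (nrow(pool) < min_block_size) break
      ch_f <- best_chain_dp(pool$rank_a, pool$rank_b, max_gap, 1L)
      ch_r <- best_chain_dp(pool$rank_a, pool$rank_b, max_gap, -1L)
      use_f <- length(ch_f) >= length(ch_r)
      chain <- if (use_f) ch_f else ch_r
      if (length(chain) < min_block_size) break
      blk <- pool[chain, , drop = FALSE]
      blk$orientation <- if (use_f) 1L else -1L
      blocks[[length(blocks) + 1L]] <- blk
      pool <- pool[-chain, , drop = FALSE]
    }
  }
  if (!length(blocks)) return(empty)
  # deterministic block ids: order by chromosome pair then first anchor rank
  ord <- order(vapply(blocks, function(b) b$chrom_a[1], character(1)),
               vapply(blocks, function(b) b$chrom_b[1], character(1)),
               vapply(blocks, function(b) min(b$rank_a), integer(1)))
  blocks <- blocks[ord]
  out <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    b$block_id <- sprintf("B%03d", i)
    b$n_anchors <- nrow(b)
    b
  }))
  rownames(out) <- NULL
  out[c("block_id", "chrom_a", "chrom_b", "gene_a", "gene_b",
        "rank_a", "rank_b", "n_anchors", "orientation")]
}

#' Classify the duplication type of each family member
#'
#' Each gene receives exactly one label under the precedence
#' `wgd_segmental > tandem > proximal > dispersed > singleton`:
#' an anchor in any collinear block is segmental/WGD; otherwise a paralog
#' at gene-rank distance 1 on the same chromosome makes a tandem; a
#' paralog within `proximal_max_rank_gap` ranks makes a proximal; any
#' remaining paralog makes a dispersed; a gene with no paralog is a
#' singleton. When `nbs_only = TRUE` (the default) only paralog pairs in
#' which both genes belong to `nbs_genes` count for tandem/proximal/
#' dispersed evidence, since the family's own expansion is what is being
#' classified; the full gene set still defines ranks.
#'
#' @param nbs_genes Gene-model table of the family members to label (ranks
#'   from the genome-wide table).
#' @param pairs Paralog pairs ([find_paralog_pairs()]).
#' @param blocks Collinear blocks ([detect_collinear_blocks()]).
#' @param proximal_max_rank_gap Rank-distance ceiling for proximal
#'   (default 20).
#' @param nbs_only Restrict pair evidence to within-family pairs.
#' @return `data.frame` with `gene_id`, `label`.
#' @export
classify_duplications <- function(nbs_genes, pairs, blocks,
                                  proximal_max_rank_gap = 20,
                                  nbs_only = TRUE) {
  ids <- nbs_genes$gene_id
  label <- setNames(rep("singleton", length(ids)), ids)
  anchor_genes <- unique(c(blocks$gene_a, blocks$gene_b))
  p <- pairs
  if (nbs_only)
    p <- p[p$gene_a %in% ids & p$gene_b %in% ids, , drop = FALSE]
  chrom <- setNames(nbs_genes$chrom, ids)
  rank <- setNames(nbs_genes$rank, ids)
  has_pair <- unique(c(p$gene_a, p$gene_b))
  same_chrom <- p[!is.na(chrom[p$gene_a]) & !is.na(chrom[p$gene_b]) &
                    chrom[p$gene_a] == chrom[p$gene_b], , drop = FALSE]
  gap <- abs(rank[same_chrom$gene_a] - rank[same_chrom$gene_b])
  tandem_genes <- unique(c(same_chrom$gene_a[gap == 1L],
                           same_chrom$gene_b[gap == 1L]))
  prox_genes <- unique(c(same_chrom$gene_a[gap >= 2L & gap <= proximal_max_rank_gap],
                         same_chrom$gene_b[gap >= 2L & gap <= proximal_max_rank_gap]))
  label[ids %in% has_pair] <- "dispersed"
  label[ids %in% prox_genes] <- "proximal"
  label[ids %in% tandem_genes] <- "tandem"
  label[ids %in% anchor_genes] <- "wgd_segmental"
  data.frame(gene_id = ids, label = unname(label[ids]),
             stringsAsFactors = FALSE)
}

#' Tabulate duplication-type counts and shares
#'
#' @param labels Output of [classify_duplications()].
#' @return `data.frame` with `label`, `count`, `percent` (whole-percent
#'   display convention).
#' @export
summarize_duplications <- function(labels) {
  lev <- c("wgd_segmental", "tandem", "proximal", "dispersed", "singleton")
  tab <- table(factor(labels$label, levels = lev))
  data.frame(label = lev, count = as.integer(tab),
             percent = round(100 * as.integer(tab) / max(1L, nrow(labels))),
             stringsAsFactors = FALSE)
}
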