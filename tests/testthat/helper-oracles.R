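# Small builders and independent oracles used across the suite.

mk_genes <- function(chrom, start, end = start + 999L,
                     gene_id = sprintf("g%03d", seq_along(start))) {
  as_gene_models(data.frame(gene_id = gene_id, chrom = chrom,
                            start = as.integer(start), end = as.integer(end),
                            strand = rep_len("+", length(start)),
                            stringsAsFactors = FALSE))
}

mk_hits <- function(query_id, target = "NB-ARC", evalue = 1e-30,
                    score = 100, q_start = 1L, q_end = 100L, source = "hmm") {
  n <- length(query_id)
  data.frame(query_id = query_id,
             target = rep_len(target, n),
             evalue = rep_len(evalue, n),
             score = rep_len(score, n),
             q_start = rep_len(q_start, n),
             q_end = rep_len(q_end, n),
             source = rep_len(source, n),
             stringsAsFactors = FALSE)
}

mk_annot <- function(domains, width = 100L) {
  starts <- cumsum(c(1L, rep(width + 10L, length(domains) - 1L)))
  data.frame(domain = domains, q_start = starts,
             q_end = starts + width - 1L, evalue = 1e-20,
             source = "cdd", stringsAsFactors = FALSE)
}

# O(n^2) pairwise-linkage + union-find oracle for the cluster caller.
oracle_clusters <- function(genes, window, anchor = "interval") {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (genes$chrom[i] != genes$chrom[j]) next
    linked <- if (anchor == "interval") {
      max(genes$start[i], genes$start[j]) -
        min(genes$end[i], genes$end[j]) <= window
    } else {
      abs(genes$start[i] - genes$start[j]) <= window
    }
    if (linked) union_(i, j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(genes$gene_id, comp)
}

# canonical form of a gene partition for comparison
partition_key <- function(groups) {
  sets <- lapply(groups, sort)
  paste(sort(vapply(sets, paste, character(1), collapse = ",")),
        collapse = ";")
}

# Exhaustive best-chain oracle: depth-first enumeration of every valid
# chain (strictly increasing x with gap <= max_gap; y strictly monotone in
# a consistent direction with gap <= max_gap), returning the maximum chain
# length. Feasible for n <= 15.
oracle_best_chain <- function(x, y, max_gap) {
  n <- length(x)
  best <- 0L
  extend <- function(last, size, dir) {
    best <<- max(best, size)
    for (j in seq_len(n)) {
      dx <- x[j] - x[last]
      if (dx <= 0L || dx > max_gap) next
      dy <- y[j] - y[last]
      ok <- (dir == 1L && dy > 0L && dy <= max_gap) ||
        (dir == -1L && dy < 0L && -dy <= max_gap)
      if (ok) extend(j, size + 1L, dir)
    }
  }
  for (s in seq_len(n)) {
    extend(s, 1L, 1L)
    extend(s, 1L, -1L)
  }
  best
}

# sum of anchors over greedily extracted chains of length >= min_size,
# oracle counterpart of detect_collinear_blocks on one chromosome pair
oracle_block_genes <- function(x, y, max_gap, min_size) {
  total <- 0L
  repeat {
    if (length(x) < min_size) break
    b <- oracle_best_chain(x, y, max_gap)
    if (b < min_size) break
    # remove one maximum chain: re-enumerate to find its members
    n <- length(x)
    best_chain <- NULL
    extend <- function(chain, dir) {
      if (length(chain) > length(best_chain)) best_chain <<- chain
      last <- chain[length(chain)]
      for (j in seq_len(n)) {
        dx <- x[j] - x[last]
        if (dx <= 0L || dx > max_gap) next
        dy <- y[j] - y[last]
        ok <- (dir == 1L && dy > 0L && dy <= max_gap) ||
          (dir == -1L && dy < 0L && -dy <= max_gap)
        if (ok) extend(c(chain, j), dir)
      }
    }
    for (s in seq_len(n)) { extend(s, 1L); extend(s, -1L) }
    total <- total + length(best_chain)
    x <- x[-best_chain]; y <- y[-best_chain]
  }
  total
}

# default-config fixture shared by the slower tests (built once per run)
fixture_env <- new.env()
default_fixture <- function(seed = 42L) {
  key <- paste0("fix", seed)
  if (is.null(fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("nbsfix", seed))
    sim <- simulate_survey(sim_config(seed), dir)
    fixture_env[[key]] <- list(dir = dir, sim = sim)
  }
  fixture_env[[key]]
}

fixture_config <- function(dir) {
  f <- function(x) file.path(dir, x)
  list(inputs = list(gff = f("genome.gff3"), hmm_hits = f("hmm_hits.tsv"),
                     blast_hits = f("blast_hits.tsv"),
                     rescan_hits = f("rescan_hits.tsv"),
                     domain_hits = f("domain_hits.tsv"),
                     subclass_hints = f("subclass_hints.tsv"),
                     allvall = f("allvall.tsv"),
                     chromosomes = f("chromosomes.tsv"),
                     tree = f("tree.nwk"),
                     tree_subclasses = f("tree_subclasses.tsv"),
                     expr = f("expr.tsv")))
}
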