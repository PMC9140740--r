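test_that("cluster calling chains genes within the flanking window", {
  # gaps: 50kb (link), 300kb (break), 100kb (link)
  g <- mk_genes("chr1", c(1e5, 1.51e5 + 999, 5.6e5, 6.7e5))
  asg <- call_clusters(g, window = 250000)
  expect_equal(nrow(asg$loci), 2L)
  expect_equal(asg$loci$n_genes, c(2L, 2L))
  expect_equal(asg$loci$kind, c("cluster", "cluster"))
  expect_equal(unname(asg$membership[g$gene_id]),
               asg$loci$locus_id[c(1, 1, 2, 2)])

  # distance exactly equal to the window still links; one base more breaks
  h <- mk_genes("chr1", c(1e5, 1e5 + 999 + 250000))
  expect_equal(call_clusters(h, 250000)$loci$kind, c("cluster"))
  h2 <- mk_genes("chr1", c(1e5, 1e5 + 999 + 250000 + 1))
  expect_equal(call_clusters(h2, 250000)$loci$kind,
               c("singleton", "singleton"))
})

test_that("chromosome boundaries always break clusters", {
  g <- mk_genes(c("chr1", "chr2"), c(1e5, 1.2e5))
  asg <- call_clusters(g, window = 250000)
  expect_equal(asg$loci$kind, c("singleton", "singleton"))
})

test_that("linkage is transitive: a chain of near genes is one locus", {
  g <- mk_genes("chr1", seq(1e5, by = 2e5, length.out = 10))
  asg <- call_clusters(g, window = 250000)
  expect_equal(nrow(asg$loci), 1L)
  expect_equal(asg$loci$n_genes, 10L)
  # yet no two non-adjacent genes are within the window of each other
  expect_true(all(g$start[3:10] - g$end[1:8] > 250000))
})

test_that("a long gene can bridge neighbours the start-anchored rule splits", {
  g <- as_gene_models(data.frame(
    gene_id = c("long", "right"), chrom = "chr1",
    start = c(100000L, 650000L), end = c(500000L, 651000L),
    strand = "+", stringsAsFactors = FALSE))
  expect_equal(call_clusters(g, 250000, anchor = "interval")$loci$kind,
               "cluster")
  expect_equal(call_clusters(g, 250000, anchor = "start")$loci$kind,
               c("singleton", "singleton"))
})

test_that("empty and single-gene inputs are handled", {
  expect_equal(nrow(call_clusters(mk_genes(character(0),
                                           integer(0)))$loci), 0L)
  one <- call_clusters(mk_genes("chr1", 1e5))
  expect_equal(one$loci$kind, "singleton")
  expect_equal(unname(one$membership), "L001")
})

test_that("sweep agrees with a pairwise union-find oracle on random maps", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:60, 1)
    g <- mk_genes(sample(paste0("chr", 1:4), n, replace = TRUE),
                  sample.int(3e6, n),
                  gene_id = sprintf("g%03d", sample.int(999, n)))
    g$end <- g$start + sample.int(5000, n)
    g <- as_gene_models(g)
    w <- sample(c(0, 1e4, 1e5, 2.5e5), 1)
    for (anc in c("interval", "start")) {
      asg <- call_clusters(g, window = w, anchor = anc)
      got <- strsplit(asg$loci$members, ",")
      expect_equal(partition_key(got), partition_key(oracle_clusters(g, w, anc)))
    }
  }
})

test_that("locus spans cover members and ids are ordered by position", {
  fix <- default_fixture()
  g <- fix$sim$genome$genes
  nbs <- g[g$gene_id %in% fix$sim$genome$truth$nbs_ids, ]
  asg <- call_clusters(nbs)
  for (i in seq_len(nrow(asg$loci))) {
    mem <- strsplit(asg$loci$members[i], ",")[[1]]
    rows <- nbs[match(mem, nbs$gene_id), ]
    expect_true(all(rows$chrom == asg$loci$chrom[i]))
    expect_equal(min(rows$start), asg$loci$span_start[i])
    expect_equal(max(rows$end), asg$loci$span_end[i])
  }
  expect_false(is.unsorted(order(asg$loci$chrom, asg$loci$span_start)))
})

test_that("planted loci are recovered exactly", {
  fix <- default_fixture()
  tr <- fix$sim$genome$truth
  g <- fix$sim$genome$genes
  nbs <- g[g$gene_id %in% tr$nbs_ids, ]
  asg <- call_clusters(nbs)
  got <- distribution_summary(asg)
  expect_equal(got$totals$clusters, tr$n_clusters)
  expect_equal(got$totals$singletons, tr$n_singleton_loci)
  expect_equal(got$totals$loci, tr$n_clusters + tr$n_singleton_loci)
  sizes <- sort(asg$loci$n_genes[asg$loci$kind == "cluster"])
  expect_equal(sizes, sort(tr$cluster_sizes))
  # cluster co-membership matches the planted partition
  planted <- split(names(tr$cluster_id), tr$cluster_id)
  called <- strsplit(asg$loci$members[asg$loci$kind == "cluster"], ",")
  expect_equal(partition_key(called), partition_key(planted))
})

test_that("distribution totals satisfy their accounting identities", {
  fix <- default_fixture()
  g <- fix$sim$genome$genes
  nbs <- g[g$gene_id %in% fix$sim$genome$truth$nbs_ids, ]
  chroms <- data.frame(chrom = sort(unique(g$chrom)),
                       length = tapply(g$end, g$chrom, max)[sort(unique(g$chrom))],
                       stringsAsFactors = FALSE)
  ds <- distribution_summary(call_clusters(nbs), chromosomes = chroms)
  expect_equal(sum(ds$per_chromosome$n_genes), ds$totals$genes)
  expect_equal(sum(ds$per_chromosome$n_loci), ds$totals$loci)
  expect_equal(ds$totals$clustered_genes + ds$totals$singletons,
               ds$totals$genes)
  # empty chromosome is present with zero genes
  expect_true("chr22" %in% ds$per_chromosome$chrom)
  expect_equal(ds$per_chromosome$n_genes[ds$per_chromosome$chrom == "chr22"], 0L)
  # per-chromosome counts equal the planted map (truth follows the
  # chromosome table's order)
  planted <- fix$sim$genome$truth$per_chromosome_nbs
  got <- setNames(ds$per_chromosome$n_genes, ds$per_chromosome$chrom)
  expect_equal(unname(got[fix$sim$genome$chromosomes$chrom]), planted)
})

test_that("rounding conventions: mean size to 2 decimals reads as reported", {
  loci <- data.frame(
    locus_id = sprintf("L%03d", 1:62), chrom = "chr1",
    kind = rep(c("singleton", "cluster"), c(44, 18)),
    n_genes = c(rep(1L, 44), c(10L, 8L, 7L, 7L, 6L, 6L, 5L, 5L, 5L,
                               4L, 4L, 4L, 4L, 3L, 3L, 2L, 2L, 2L)),
    span_start = 1L, span_end = 2L, members = "x",
    stringsAsFactors = FALSE)
  ds <- distribution_summary(list(loci = loci))
  expect_equal(ds$totals$genes, 131L)
  expect_equal(ds$totals$clustered_genes, 87L)
  expect_equal(round(ds$totals$mean_cluster_size, 2), 4.83)
  expect_equal(round(ds$totals$mean_cluster_size), 5)
  expect_equal(ds$totals$max_cluster_size, 10L)
  expect_equal(round(ds$totals$percent_clustered, 1), 66.4)
})

test_that("length correlation: recovers a planted monotone trend", {
  counts <- data.frame(chrom = paste0("chr", 1:10), n_genes = 1:10,
                       stringsAsFactors = FALSE)
  lens <- data.frame(chrom = paste0("chr", 1:10),
                     length = (1:10) * 1e6, stringsAsFactors = FALSE)
  lc <- length_correlation(counts, lens)
  expect_equal(lc$rho, 1)
  expect_false(lc$degenerate)

  lens2 <- lens; lens2$length <- rev(lens2$length)
  expect_equal(length_correlation(counts, lens2)$rho, -1)

  counts0 <- counts; counts0$n_genes <- 5L
  expect_true(length_correlation(counts0, lens)$degenerate)

  expect_error(length_correlation(counts[1:2, ], lens[1:2, ]),
               class = "nbsurvey_insufficient_data_error")
})

test_that("simulated genome shows no significant length correlation", {
  fix <- default_fixture()
  g <- fix$sim$genome$genes
  nbs <- g[g$gene_id %in% fix$sim$genome$truth$nbs_ids, ]
  chroms <- data.frame(chrom = sort(unique(g$chrom)),
                       length = tapply(g$end, g$chrom, max)[sort(unique(g$chrom))],
                       stringsAsFactors = FALSE)
  ds <- distribution_summary(call_clusters(nbs), chromosomes = chroms)
  lc <- length_correlation(ds$per_chromosome, chroms)
  expect_gt(lc$p_value, 0.05)
})
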