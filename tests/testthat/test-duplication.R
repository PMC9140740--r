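norm_pairs <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  sort(unique(key))
}

test_that("paralog pairs drop self-hits, weak hits, and duplicates", {
  sim <- mk_hits(c("a", "a", "a", "b"), source = "blast")
  sim$target <- c("a", "b", "c", "a")
  sim$evalue <- c(0, 1e-50, 1e-5, 1e-40)
  sim$score <- c(999, 500, 300, 480)
  p <- find_paralog_pairs(sim)
  # self-hit gone, weak a-c gone, reciprocal a-b collapsed
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene_a, "a")
  expect_equal(p$gene_b, "b")
  # under a stricter ceiling only the self-hit survives, so no pairs remain
  expect_equal(nrow(find_paralog_pairs(sim, evalue_max = 1e-60)), 0L)
})

test_that("each query keeps only its top hits by bitscore", {
  sim <- mk_hits(rep("q", 8), source = "blast")
  sim$target <- paste0("t", 1:8)
  sim$evalue <- 1e-40
  sim$score <- c(800, 700, 600, 500, 400, 300, 200, 100)
  p <- find_paralog_pairs(sim, top_n_hits = 5)
  expect_equal(sort(p$gene_b), paste0("t", 1:5))
  p3 <- find_paralog_pairs(sim, top_n_hits = 3)
  expect_equal(sort(p3$gene_b), paste0("t", 1:3))
})

test_that("chain dynamic program matches exhaustive enumeration", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    x <- sample.int(40, n)
    y <- sample.int(40, n, replace = TRUE)
    gap <- sample(c(3L, 10L, 25L), 1)
    got <- max(length(best_chain_dp(x, y, gap, 1L)),
               length(best_chain_dp(x, y, gap, -1L)))
    expect_equal(got, oracle_best_chain(x, y, gap))
  }
})

test_that("a planted diagonal is reported as one collinear block", {
  g <- mk_genes(rep(c("c1", "c2"), each = 10),
                rep(seq(1e5, by = 5e5, length.out = 10), 2),
                gene_id = c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  pairs <- data.frame(gene_a = sprintf("a%02d", 2:7),
                      gene_b = sprintf("b%02d", 3:8),
                      stringsAsFactors = FALSE)
  blk <- detect_collinear_blocks(pairs, g)
  expect_equal(unique(blk$block_id), "B001")
  expect_equal(nrow(blk), 6L)
  expect_equal(unique(blk$orientation), 1L)

  # reversed second axis: antiparallel diagonal, still one block
  rpairs <- pairs
  rpairs$gene_b <- rev(rpairs$gene_b)
  rblk <- detect_collinear_blocks(rpairs, g)
  expect_equal(nrow(rblk), 6L)
  expect_equal(unique(rblk$orientation), -1L)

  # four anchors are below the block-size floor
  expect_equal(nrow(detect_collinear_blocks(pairs[1:4, ], g)), 0L)
  expect_error(detect_collinear_blocks(
    data.frame(gene_a = "a01", gene_b = "zz", stringsAsFactors = FALSE), g),
    class = "nbsurvey_validation_error")
})

test_that("rank gaps beyond the ceiling split chains into separate blocks", {
  n <- 80
  g <- mk_genes(rep(c("c1", "c2"), each = n),
                rep(seq(1e5, by = 5e5, length.out = n), 2),
                gene_id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)))
  ranks <- c(1:5, 41:45)  # dx = 36 between the two runs
  pairs <- data.frame(gene_a = sprintf("a%02d", ranks),
                      gene_b = sprintf("b%02d", ranks),
                      stringsAsFactors = FALSE)
  blk <- detect_collinear_blocks(pairs, g, max_gap = 25)
  expect_equal(length(unique(blk$block_id)), 2L)
  expect_equal(as.integer(table(blk$block_id)), c(5L, 5L))
  # a permissive gap ceiling reunites them
  blk2 <- detect_collinear_blocks(pairs, g, max_gap = 40)
  expect_equal(length(unique(blk2$block_id)), 1L)
})

test_that("duplication labels follow the documented precedence", {
  g <- mk_genes("c1", seq(1e5, by = 5e5, length.out = 30),
                gene_id = sprintf("g%02d", 1:30))
  fam <- g[g$gene_id %in% sprintf("g%02d", c(1, 2, 5, 8, 29, 30)), ]
  pairs <- data.frame(
    gene_a = c("g01", "g05", "g29"),
    gene_b = c("g02", "g08", "g30"),  # gaps 1 (tandem), 3 (proximal), 1
    stringsAsFactors = FALSE)
  blocks <- data.frame(gene_a = "g29", gene_b = "g30",
                       stringsAsFactors = FALSE)
  lab <- classify_duplications(fam, pairs, blocks)
  got <- setNames(lab$label, lab$gene_id)
  expect_equal(unname(got[c("g01", "g02")]), c("tandem", "tandem"))
  expect_equal(unname(got[c("g05", "g08")]), c("proximal", "proximal"))
  # block anchors outrank their own tandem signal
  expect_equal(unname(got[c("g29", "g30")]),
               c("wgd_segmental", "wgd_segmental"))

  # a gap just past the proximal ceiling demotes to dispersed
  fam2 <- g[g$gene_id %in% c("g01", "g25"), ]
  p2 <- data.frame(gene_a = "g01", gene_b = "g25", stringsAsFactors = FALSE)
  lab2 <- classify_duplications(fam2, p2, blocks[0, ])
  expect_equal(unique(lab2$label), "dispersed")
  lab3 <- classify_duplications(fam2, p2, blocks[0, ],
                                proximal_max_rank_gap = 24)
  expect_equal(unique(lab3$label), "proximal")
})

test_that("pairs with non-family genes only count when nbs_only is off", {
  g <- mk_genes(c("c1", "c2"), c(1e5, 1e5), gene_id = c("fam", "bg"))
  fam <- g[g$gene_id == "fam", ]
  p <- data.frame(gene_a = "bg", gene_b = "fam", stringsAsFactors = FALSE)
  strict <- classify_duplications(fam, p, data.frame(gene_a = character(),
                                                     gene_b = character()))
  expect_equal(strict$label, "singleton")
  loose <- classify_duplications(fam, p, data.frame(gene_a = character(),
                                                    gene_b = character()),
                                 nbs_only = FALSE)
  expect_equal(loose$label, "dispersed")
})

test_that("duplication table uses whole-percent display shares", {
  labels <- data.frame(
    gene_id = sprintf("g%03d", 1:131),
    label = rep(c("tandem", "dispersed", "proximal", "wgd_segmental"),
                c(28, 18, 15, 70)), stringsAsFactors = FALSE)
  tab <- summarize_duplications(labels)
  expect_equal(sum(tab$count), 131L)
  expect_equal(tab$percent[tab$label == "tandem"], 21)
  expect_equal(tab$percent[tab$label == "wgd_segmental"], 53)
  expect_equal(tab$count[tab$label == "singleton"], 0L)
})

test_that("planted duplication history is recovered from the raw tables", {
  fix <- default_fixture()
  g <- fix$sim$genome
  pairs <- find_paralog_pairs(g$allvall)
  expect_equal(norm_pairs(pairs$gene_a, pairs$gene_b),
               norm_pairs(g$truth$pairs$gene_a, g$truth$pairs$gene_b))
  blocks <- detect_collinear_blocks(pairs, g$genes)
  expect_setequal(unique(c(blocks$gene_a, blocks$gene_b)),
                  unique(c(g$truth$blocks$gene_a, g$truth$blocks$gene_b)))
  fam <- g$genes[g$genes$gene_id %in% g$truth$nbs_ids, ]
  lab <- classify_duplications(fam, pairs, blocks)
  expect_equal(setNames(lab$label, lab$gene_id)[g$truth$nbs_ids],
               g$truth$dup_label)
  tab <- summarize_duplications(lab)
  expect_equal(setNames(tab$count, tab$label)[names(g$truth$dup_counts)],
               setNames(as.integer(g$truth$dup_counts),
                        names(g$truth$dup_counts)))
})

test_that("block precedence survives adversarial tandem-like anchors", {
  cfg <- sim_config(seed = 9, adversarial = TRUE)
  g <- simulate_genome(cfg)
  pairs <- find_paralog_pairs(g$allvall)
  blocks <- detect_collinear_blocks(pairs, g$genes)
  fam <- g$genes[g$genes$gene_id %in% g$truth$nbs_ids, ]
  lab <- classify_duplications(fam, pairs, blocks)
  expect_equal(setNames(lab$label, lab$gene_id)[g$truth$nbs_ids],
               g$truth$dup_label)
  # the adversarial run really does carry rank-adjacent paralog pairs
  rank <- setNames(g$genes$rank, g$genes$gene_id)
  chrom <- setNames(g$genes$chrom, g$genes$gene_id)
  adj <- chrom[pairs$gene_a] == chrom[pairs$gene_b] &
    abs(rank[pairs$gene_a] - rank[pairs$gene_b]) == 1L
  seg <- names(g$truth$dup_label)[g$truth$dup_label == "wgd_segmental"]
  expect_true(any(adj & pairs$gene_a %in% seg & pairs$gene_b %in% seg))
})
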