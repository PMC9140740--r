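test_that("candidate merge is a deduplicated union of both searches", {
  hmm <- mk_hits(c("a", "b", "c"))
  bls <- mk_hits(c("b", "c", "d"), source = "blast")
  expect_equal(merge_candidates(hmm, bls), c("a", "b", "c", "d"))
  expect_equal(merge_candidates(mk_hits(character(0)), mk_hits("x")), "x")
  expect_equal(merge_candidates(mk_hits(character(0)),
                                mk_hits(character(0))), character(0))
  # permissive threshold applies to both tables
  expect_equal(merge_candidates(mk_hits("a", evalue = 2.0), mk_hits("b")), "b")
})

test_that("merge handles redundant multi-hit tables", {
  set.seed(11)
  ids <- sprintf("q%03d", sample(137, 200, replace = TRUE))
  half <- sample(200, 100)
  got <- merge_candidates(mk_hits(ids[half]), mk_hits(ids[-half]))
  expect_equal(length(got), length(unique(ids)))
})

test_that("strict re-scan keeps only genes with a sub-threshold NBS hit", {
  cands <- c("keep", "drop", "nohit")
  rescan <- mk_hits(c("keep", "drop", "stranger"),
                    evalue = c(5e-5, 2e-3, 1e-30))
  expect_warning(got <- strict_rescan_filter(cands, rescan),
                 "non-candidate")
  expect_equal(got, "keep")
})

test_that("strict filter is monotone in the threshold", {
  set.seed(3)
  cands <- sprintf("g%02d", 1:50)
  rescan <- mk_hits(sample(cands, 120, replace = TRUE),
                    evalue = 10^-runif(120, 0, 12))
  prev <- character(0)
  for (thr in 10^seq(-12, 0, by = 2)) {
    cur <- strict_rescan_filter(cands, rescan, threshold = thr)
    expect_true(all(prev %in% cur))
    expect_true(all(cur %in% cands))
    prev <- cur
  }
})

test_that("planted cohort: exactly the true NBS genes survive the re-scan", {
  fix <- default_fixture()
  g <- fix$sim$genome
  cands <- merge_candidates(g$hmm_hits, g$blast_hits)
  expect_true(all(g$truth$decoys %in% cands))
  confirmed <- strict_rescan_filter(cands, g$rescan_hits)
  expect_equal(confirmed, g$truth$nbs_ids)
})

test_that("architecture calls follow N-terminal domain order", {
  rnrn <- classify_architecture(mk_annot(c("RPW8", "NBS", "RPW8", "NBS")), "g")
  expect_equal(rnrn$arch_string, "RNRN")
  expect_equal(rnrn$subclass, "RNL")
  expect_false(rnrn$intact)  # no LRR

  tnl <- classify_architecture(mk_annot(c("TIR", "NBS", "LRR")), "g")
  expect_equal(tnl$arch_string, "TNL")
  expect_true(tnl$intact)

  fused <- classify_architecture(mk_annot(c("TIR", "NBS", "LRR", "MARCH1")), "g")
  expect_equal(fused$integrated_domains,
               data.frame(name = "MARCH1", terminus = "C",
                          stringsAsFactors = FALSE))
  expect_equal(fused$arch_string, "TNL-MARCH1(C)")
  nfused <- classify_architecture(mk_annot(c("WRKY", "TIR", "NBS", "LRR")), "g")
  expect_equal(nfused$integrated_domains$terminus, "N")

  expect_error(classify_architecture(mk_annot(c("TIR", "LRR")), "g"),
               class = "nbsurvey_precondition_error")
})

test_that("subclass precedence is RPW8 > TIR > CC and hints resolve truncations", {
  both <- classify_architecture(mk_annot(c("CC", "TIR", "NBS", "LRR")), "g")
  expect_equal(both$subclass, "TNL")
  rp <- classify_architecture(mk_annot(c("TIR", "RPW8", "NBS")), "g")
  expect_equal(rp$subclass, "RNL")

  bare <- classify_architecture(mk_annot(c("NBS", "LRR")), "g")
  expect_equal(bare$subclass, "NL-ambiguous")
  hinted <- classify_architecture(mk_annot(c("NBS", "LRR")), "g",
                                  profile_subclass = "TNL")
  expect_equal(hinted$subclass, "TNL")
  expect_false(hinted$intact)
})

test_that("architecture calls depend on segment order, not coordinates", {
  a1 <- mk_annot(c("TIR", "NBS", "LRR", "WRKY"))
  a2 <- a1
  a2$q_start <- a2$q_start * 7L + 3L
  a2$q_end <- a2$q_end * 7L + 9L
  c1 <- classify_architecture(a1, "g")
  c2 <- classify_architecture(a2, "g")
  expect_equal(c1[c("arch_string", "subclass", "intact")],
               c2[c("arch_string", "subclass", "intact")])
})

test_that("overlapping same-name segments merge; conflicts keep best E-value", {
  hits <- rbind(
    mk_hits("g", target = "NBS", evalue = 1e-20, q_start = 100L, q_end = 200L,
            source = "hmm"),
    mk_hits("g", target = "NBS", evalue = 1e-10, q_start = 150L, q_end = 320L,
            source = "cdd"),
    mk_hits("g", target = "LRR", evalue = 1e-30, q_start = 400L, q_end = 500L))
  ann <- build_domain_annotations(hits)[["g"]]
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$q_end[1], 320L)
  expect_equal(ann$evalue[1], 1e-20)

  conflict <- rbind(
    mk_hits("g", target = "TIR", evalue = 1e-5, q_start = 1L, q_end = 100L),
    mk_hits("g", target = "CC", evalue = 1e-15, q_start = 50L, q_end = 120L),
    mk_hits("g", target = "NBS", evalue = 1e-20, q_start = 200L, q_end = 400L))
  ann2 <- build_domain_annotations(conflict)[["g"]]
  expect_equal(ann2$domain, c("CC", "NBS"))
})

test_that("group table counts and within-subclass percentages are exact", {
  calls <- data.frame(
    gene_id = sprintf("r%02d", 1:18),
    subclass = "RNL",
    arch_string = rep(c("RNL", "RN", "N", "RNRN"), c(6, 7, 4, 1)),
    intact = rep(c(TRUE, FALSE, FALSE, FALSE), c(6, 7, 4, 1)),
    integrated_domains = "", stringsAsFactors = FALSE)
  tab <- summarize_architecture_groups(calls)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$count), 18L)
  expect_equal(tab$percent[tab$arch_string == "RNL"], 33.3)

  one <- summarize_architecture_groups(calls[1, ])
  expect_equal(one$count, 1L)
  expect_equal(one$percent, 100)
})

test_that("planted cohort: group table and subclass sums are recovered", {
  fix <- default_fixture()
  g <- fix$sim$genome
  hints <- setNames(g$hints$subclass, g$hints$gene_id)
  calls <- classify_architectures(build_domain_annotations(g$domain_hits),
                                  hints = hints)
  expect_equal(sort(unname(table(calls$subclass)[c("CNL", "TNL", "RNL")])),
               sort(unname(g$truth$subclass_counts)))
  expect_equal(sum(summarize_architecture_groups(calls)$count), 131L)
  # per-gene subclass equals the planted subclass
  expect_equal(setNames(calls$subclass, calls$gene_id)[g$truth$nbs_ids],
               g$truth$subclass)
  # planted multiplicities: one group per catalog row
  truth_groups <- fix$sim$genome$truth$arch_group_counts
  expect_equal(nrow(summarize_architecture_groups(calls)), nrow(truth_groups))
})
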