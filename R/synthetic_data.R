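#' Default planted architecture catalog
#'
#' One row per architecture group: subclass, ordered domain names
#' (comma-joined), planted gene count, and whether a reference-family
#' hint is needed to resolve the subclass (truncations lacking the
#' N-terminal domain). Defaults plant 24 groups (7 CNL, 13 TNL, 4 RNL)
#' over 40/73/18 genes, with four distinct integrated domains carried by
#' nine TNL genes (seven C-terminal, two N-terminal fusions).
#'
#' @return `data.frame` with `subclass`, `domains`, `count`, `needs_hint`.
#' @export
default_architecture_catalog <- function() {
  rows <- list(
    c("RNL", "RPW8,NBS,LRR", 6), c("RNL", "RPW8,NBS", 7),
    c("RNL", "NBS", 4), c("RNL", "RPW8,NBS,RPW8,NBS", 1),
    c("TNL", "TIR,NBS,LRR", 32), c("TNL", "TIR,NBS", 12),
    c("TNL", "NBS,LRR", 8), c("TNL", "NBS", 5),
    c("TNL", "TIR,NBS,LRR,LRR", 3), c("TNL", "TIR,TIR,NBS,LRR", 2),
    c("TNL", "TIR,NBS,TIR,NBS,LRR", 2),
    c("TNL", "TIR,NBS,LRR,WRKY", 3), c("TNL", "TIR,NBS,LRR,MARCH1", 2),
    c("TNL", "TIR,NBS,Kinase", 1), c("TNL", "TIR,NBS,LRR,BED", 1),
    c("TNL", "WRKY,TIR,NBS,LRR", 1), c("TNL", "BED,TIR,NBS,LRR", 1),
    c("CNL", "CC,NBS,LRR", 18), c("CNL", "CC,NBS", 10),
    c("CNL", "NBS,LRR", 4), c("CNL", "NBS", 2),
    c("CNL", "CC,NBS,LRR,LRR", 2), c("CNL", "CC,CC,NBS,LRR", 2),
    c("CNL", "CC,NBS,CC,NBS,LRR", 2))
  cat <- data.frame(subclass = vapply(rows, `[`, character(1), 1),
                    domains = vapply(rows, `[`, character(1), 2),
                    count = as.integer(vapply(rows, `[`, character(1), 3)),
                    stringsAsFactors = FALSE)
  first <- vapply(strsplit(cat$domains, ","), `[[`, character(1), 1)
  cat$needs_hint <- !first %in% c("TIR", "CC", "RPW8")
  cat
}

#' Build a simulation configuration
#'
#' Defaults describe the survey conditions the pipeline is meant to be
#' exercised under: a 29-chromosome genome of roughly 22,000 genes
#' carrying 131 NBS-LRR genes (40 CNL / 73 TNL / 18 RNL), 18 clusters
#' covering 87 genes, a duplication history of 28 tandem / 15 proximal /
#' 18 dispersed / 70 segmental (7 collinear blocks of 5 anchor pairs),
#' 25 decoy candidates that fail the strict NB-ARC re-scan, a 122-copy
#' ancestral gene tree over ((Nc,Nt),Ef) with an Arabidopsis-style
#' outgroup and a 102-copy CNL burst in Nc, and an expression profile in
#' which 70% of family members sit in a low (sub-1 TPM) regime.
#'
#' @param seed Integer RNG seed.
#' @param ... Named overrides of any default component.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 29L,
    genes_per_chromosome = round(seq(600, 920, length.out = 29)),
    subclass_mix = c(CNL = 40L, TNL = 73L, RNL = 18L),
    architecture_catalog = default_architecture_catalog(),
    cluster_sizes = c(10L, 8L, 7L, 7L, 6L, 6L, 5L, 5L, 5L,
                      4L, 4L, 4L, 4L, 3L, 3L, 2L, 2L, 2L),
    duplication_plan = c(tandem = 28L, dispersed = 18L,
                         proximal = 15L, wgd_segmental = 70L),
    cluster_chroms = c(11L, 15L, 18L),
    empty_chroms = 22L,
    single_gene_chroms = c(1L, 3L, 5L, 7L, 17L, 21L, 27L),
    decoy_count = 25L,
    decoy_evalue_range = c(1e-3, 0.5),
    spacing = 30000L,
    min_block_size = 5L,
    adversarial = FALSE,
    tree_plan = list(K = 122L, birth = 0.2, death = 0.05,
                     subclass_split = c(CNL = 44L, TNL = 66L, RNL = 12L),
                     ingroup = c("Ef", "Nc", "Nt"), outgroup = "At",
                     species_tree = DEFAULT_SPECIES_TREE,
                     branch_lengths = c(Ef = 1.0, NcNt = 0.5,
                                        Nc = 0.5, Nt = 0.5),
                     support_range = c(70, 100),
                     expansion = list(subclass = "CNL", species = "Nc",
                                      size = 102L)),
    expression = list(n_samples = 3L, frac_low = 0.7,
                      low_mean = 0.3, expressed_mean = 20,
                      low_threshold = 1.0))
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(cfg[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], override[[nm]])
    else cfg[[nm]] <- override[[nm]]
  }
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  n_nbs <- sum(cfg$subclass_mix)
  dp <- cfg$duplication_plan
  if (sum(dp) != n_nbs)
    nbs_stop("duplication plan must cover every NBS gene exactly once",
             "nbsurvey_config_error")
  if (sum(cfg$architecture_catalog$count) != n_nbs)
    nbs_stop("architecture catalog must cover every NBS gene",
             "nbsurvey_config_error")
  agg <- tapply(cfg$architecture_catalog$count,
                cfg$architecture_catalog$subclass, sum)
  if (!all(agg[names(cfg$subclass_mix)] == cfg$subclass_mix))
    nbs_stop("architecture catalog totals disagree with subclass mix",
             "nbsurvey_config_error")
  if (dp[["tandem"]] %% 2L != 0L)
    nbs_stop("tandem count must be even (tandem copies are planted as pairs)",
             "nbsurvey_config_error")
  if (dp[["wgd_segmental"]] %% (2L * cfg$min_block_size) != 0L)
    nbs_stop("segmental count must be a multiple of twice the block size",
             "nbsurvey_config_error")
  if (sum(cfg$cluster_sizes) > n_nbs)
    nbs_stop("cluster plan exceeds the number of NBS genes",
             "nbsurvey_config_error")
  if (any(cfg$cluster_sizes < 2L))
    nbs_stop("clusters need at least two members", "nbsurvey_config_error")
  if (length(cfg$genes_per_chromosome) != cfg$n_chromosomes)
    nbs_stop("genes_per_chromosome must have one entry per chromosome",
             "nbsurvey_config_error")
  invisible(cfg)
}

# Pack planted duplication units into the planned clusters.
# Returns NULL when infeasible for the attempted number of clustered runs.
pack_clusters <- function(sizes, n_runs_try, run_len, n_tandem_pairs,
                          n_prox_pairs, has_triple, n_disp) {
  caps <- sizes
  content <- lapply(seq_along(sizes), function(i) character(0))
  place <- function(item_size, label) {
    i <- which(caps >= item_size)[1]
    if (is.na(i)) return(FALSE)
    caps[i] <<- caps[i] - item_size
    content[[i]] <<- c(content[[i]], label)
    TRUE
  }
  for (k in seq_len(n_runs_try)) if (!place(run_len, "run")) return(NULL)
  triple_in <- has_triple && place(3L, "prox_triple")
  for (k in seq_len(n_tandem_pairs))
    if (!place(2L, "tandem_pair")) return(NULL)
  prox_in <- 0L
  for (k in seq_len(n_prox_pairs)) {
    if (!place(2L, "prox_pair")) break
    prox_in <- prox_in + 1L
  }
  disp_fill <- sum(caps)
  if (disp_fill > n_disp) return(NULL)
  for (i in seq_along(caps)) {
    content[[i]] <- c(content[[i]], rep("disp", caps[i]))
    caps[i] <- 0L
  }
  list(content = content, runs_in = n_runs_try, triple_in = triple_in,
       prox_pairs_in = prox_in, disp_in = disp_fill)
}

# Internal: work out the full placement plan (units, clusters, chromosomes)
# for a configuration. Deterministic given the config (no RNG).
plan_survey <- function(cfg) {
  dp <- cfg$duplication_plan
  run_len <- cfg$min_block_size
  n_runs <- dp[["wgd_segmental"]] %/% run_len
  n_tpairs <- dp[["tandem"]] %/% 2L
  prox <- dp[["proximal"]]
  has_triple <- prox %% 2L == 1L
  n_ppairs <- (prox - if (has_triple) 3L else 0L) %/% 2L
  n_disp <- dp[["dispersed"]]
  sizes <- sort(cfg$cluster_sizes, decreasing = TRUE)
  packed <- NULL
  for (r in seq(min(n_runs, sum(sizes) %/% run_len), 0L)) {
    packed <- pack_clusters(sizes, r, run_len, n_tpairs, n_ppairs,
                            has_triple, n_disp)
    if (!is.null(packed)) break
  }
  if (is.null(packed))
    nbs_stop("infeasible plan: planted units cannot fill the cluster sizes",
             "nbsurvey_config_error")

  units <- list()
  add_unit <- function(type, clustered, cluster_id)
    units[[length(units) + 1L]] <<- list(type = type, clustered = clustered,
                                         cluster_id = cluster_id)
  used <- c(run = 0L, tandem_pair = 0L, prox_pair = 0L,
            prox_triple = 0L, disp = 0L)
  for (ci in seq_along(packed$content)) {
    for (tp in packed$content[[ci]]) {
      add_unit(tp, TRUE, ci)
      used[tp] <- used[tp] + 1L
    }
  }
  for (k in seq_len(n_runs - used[["run"]])) add_unit("run", FALSE, NA)
  if (has_triple && !packed$triple_in) add_unit("prox_triple", FALSE, NA)
  for (k in seq_len(n_ppairs - used[["prox_pair"]])) add_unit("prox_pair", FALSE, NA)
  for (k in seq_len(n_disp - used[["disp"]])) add_unit("disp", FALSE, NA)
  if (n_tpairs != used[["tandem_pair"]])
    nbs_stop("infeasible plan: tandem pairs must all be clustered",
             "nbsurvey_config_error")

  units <- do.call(rbind, lapply(seq_along(units), function(i)
    data.frame(unit_id = i, type = units[[i]]$type,
               clustered = units[[i]]$clustered,
               cluster_id = units[[i]]$cluster_id,
               stringsAsFactors = FALSE)))
  units$n_genes <- c(run = run_len, tandem_pair = 2L, prox_pair = 2L,
                     prox_triple = 3L, disp = 1L)[units$type]

  # chromosome assignment
  units$chrom <- NA_integer_
  cl_chrom <- cfg$cluster_chroms[(seq_along(sizes) - 1L) %%
                                   length(cfg$cluster_chroms) + 1L]
  units$chrom[units$clustered] <- cl_chrom[units$cluster_id[units$clustered]]
  pool <- setdiff(seq_len(cfg$n_chromosomes),
                  c(cfg$cluster_chroms, cfg$empty_chroms,
                    cfg$single_gene_chroms))
  free <- units$unit_id[!units$clustered]
  types <- units$type[match(free, units$unit_id)]
  singles <- free[types == "disp"]
  others <- free[types != "disp"]
  for (i in seq_along(others))
    units$chrom[units$unit_id == others[i]] <- pool[(i - 1L) %% length(pool) + 1L]
  n_single_chrom <- length(cfg$single_gene_chroms)
  for (i in seq_along(singles)) {
    ch <- if (i <= n_single_chrom) cfg$single_gene_chroms[i]
    else pool[(length(others) + i - 1L) %% length(pool) + 1L]
    units$chrom[units$unit_id == singles[i]] <- ch
  }

  # pair collinear run sides into blocks across different chromosomes
  run_ids <- units$unit_id[units$type == "run"]
  blocks <- list()
  remaining <- run_ids
  while (length(remaining) >= 2L) {
    a <- remaining[1]
    cand <- remaining[-1][units$chrom[match(remaining[-1], units$unit_id)] !=
                            units$chrom[units$unit_id == a]]
    if (!length(cand))
      nbs_stop("infeasible plan: cannot pair collinear runs across chromosomes",
               "nbsurvey_config_error")
    b <- cand[1]
    blocks[[length(blocks) + 1L]] <- c(a, b)
    remaining <- setdiff(remaining, c(a, b))
  }

  # pair dispersed genes across different chromosomes
  disp_ids <- units$unit_id[units$type == "disp"]
  disp_pairs <- list()
  remaining <- disp_ids
  while (length(remaining) >= 2L) {
    a <- remaining[1]
    cand <- remaining[-1][units$chrom[match(remaining[-1], units$unit_id)] !=
                            units$chrom[units$unit_id == a]]
    if (!length(cand))
      nbs_stop("infeasible plan: cannot pair dispersed copies across chromosomes",
               "nbsurvey_config_error")
    b <- cand[1]
    disp_pairs[[length(disp_pairs) + 1L]] <- c(a, b)
    remaining <- setdiff(remaining, c(a, b))
  }
  if (length(remaining))
    nbs_stop("infeasible plan: dispersed count must be even",
             "nbsurvey_config_error")

  list(units = units, blocks = blocks, disp_pairs = disp_pairs,
       cluster_sizes = sizes, run_len = run_len)
}

# slot pattern of one unit: TRUE = NBS gene, FALSE = background gene
unit_pattern <- function(type, clustered, run_len, adversarial = FALSE) {
  nbs <- TRUE; bg <- FALSE
  switch(type,
    tandem_pair = c(nbs, nbs),
    prox_pair = if (clustered) c(nbs, bg, nbs)
                else c(nbs, rep(bg, 14L), nbs),
    prox_triple = if (clustered) c(nbs, bg, nbs, bg, nbs)
                  else c(nbs, rep(bg, 12L), nbs, rep(bg, 12L), nbs),
    disp = nbs,
    run = {
      sep <- if (adversarial) 0L else if (clustered) 1L else 12L
      head(rep(c(nbs, rep(bg, sep)), run_len), (1L + sep) * run_len - sep)
    },
    nbs_stop(paste("unknown unit type", type), "nbsurvey_config_error"))
}

#' Simulate a genome annotation with planted NBS-LRR structure
#'
#' Realizes the configuration into an in-memory genome: a gene-model
#' table over all chromosomes, planted NBS genes with architectures,
#' clusters (internal gaps well under the 250-kb window, inter-locus gaps
#' well over it), tandem/proximal/dispersed/segmental duplication
#' histories, decoy candidates, the four homology-hit tables the
#' identification stage consumes, the all-vs-all similarity table, and a
#' ground-truth record of everything planted.
#'
#' @param cfg A `SimulationConfig` from [sim_config()].
#' @return List with `genes`, `chromosomes`, `hmm_hits`, `blast_hits`,
#'   `rescan_hits`, `domain_hits`, `hints`, `allvall`, `truth`.
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  plan <- plan_survey(cfg)
  units <- plan$units
  spacing <- cfg$spacing
  # chromosome sizes are drawn independently of the planted NBS content,
  # so family size carries no information about chromosome length
  cfg$genes_per_chromosome <- sample(cfg$genes_per_chromosome)
  gap_bg <- 31L  # background genes between units: > max_gap ranks, > 250 kb

  adv_unit <- NA_integer_
  if (isTRUE(cfg$adversarial)) {
    cand <- units$unit_id[units$type == "run" & units$clustered]
    if (length(cand)) adv_unit <- min(cand)
  }

  # ---- lay out chromosomes ----------------------------------------------
  # Units of one cluster are emitted contiguously (one background gene
  # between member units, so intra-cluster gaps stay far below the 250-kb
  # window); distinct loci are separated by `gap_bg` background genes
  # (rank gap above the collinearity gap ceiling, base gap far above the
  # cluster window).
  gene_rows <- list()
  nbs_slots <- list()   # per unit: gene ids in positional order
  counter <- 0L
  chrom_len <- integer(cfg$n_chromosomes)
  for (c_i in seq_len(cfg$n_chromosomes)) {
    chrom_units <- units[!is.na(units$chrom) & units$chrom == c_i, ,
                         drop = FALSE]
    locus_key <- ifelse(chrom_units$clustered,
                        paste0("c", chrom_units$cluster_id),
                        paste0("u", chrom_units$unit_id))
    groups <- split(seq_len(nrow(chrom_units)), locus_key)
    groups <- groups[order(vapply(groups, function(i)
      min(chrom_units$unit_id[i]), integer(1)))]
    slots <- logical(0)
    unit_at <- integer(0)
    add <- function(v, uid) {
      slots <<- c(slots, v)
      unit_at <<- c(unit_at, ifelse(v, uid, NA_integer_))
    }
    add(rep(FALSE, gap_bg), NA_integer_)
    for (grp in groups) {
      for (k in seq_along(grp)) {
        u <- chrom_units[grp[k], ]
        if (k > 1L) add(FALSE, NA_integer_)
        add(unit_pattern(u$type, u$clustered, plan$run_len,
                         identical(u$unit_id, adv_unit)),
            u$unit_id)
      }
      add(rep(FALSE, gap_bg), NA_integer_)
    }
    n_extra <- max(0L, cfg$genes_per_chromosome[c_i] - sum(!slots))
    add(rep(FALSE, n_extra), NA_integer_)
    n <- length(slots)
    starts <- 1000L + (seq_len(n) - 1L) * spacing +
      as.integer(runif(n, 0, 5000))
    lens <- sample(1000:5000, n, replace = TRUE)
    ids <- sprintf("g%05d", counter + seq_len(n))
    counter <- counter + n
    gene_rows[[c_i]] <- data.frame(
      gene_id = ids, chrom = sprintf("chr%02d", c_i),
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    chrom_len[c_i] <- starts[n] + lens[n] + 200000L
    for (uid in unique(unit_at[!is.na(unit_at)]))
      nbs_slots[[as.character(uid)]] <- ids[!is.na(unit_at) & unit_at == uid]
  }
  genes <- as_gene_models(do.call(rbind, gene_rows))
  chromosomes <- data.frame(chrom = sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
                            length = chrom_len, stringsAsFactors = FALSE)

  # ---- planted NBS genes: duplication labels, pairs, blocks --------------
  unit_genes <- nbs_slots[as.character(units$unit_id)]
  nbs_ids <- unlist(unit_genes, use.names = FALSE)
  dup_label <- character(0)
  pair_rows <- list()
  for (ui in seq_len(nrow(units))) {
    g <- unit_genes[[ui]]
    tp <- units$type[ui]
    lab <- c(run = "wgd_segmental", tandem_pair = "tandem",
             prox_pair = "proximal", prox_triple = "proximal",
             disp = "dispersed")[tp]
    dup_label[g] <- lab
    if (tp %in% c("tandem_pair", "prox_pair"))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = g[1], gene_b = g[2], stringsAsFactors = FALSE)
    if (tp == "prox_triple")
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = g[c(1, 2)], gene_b = g[c(2, 3)], stringsAsFactors = FALSE)
    if (identical(units$unit_id[ui], adv_unit))
      # adversarial mode: adjacent collinear anchors are also paralog
      # pairs, so block precedence must beat the tandem signal
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = g[-length(g)], gene_b = g[-1], stringsAsFactors = FALSE)
  }
  anchor_rows <- list()
  for (bi in seq_along(plan$blocks)) {
    ab <- plan$blocks[[bi]]
    ga <- unit_genes[[which(units$unit_id == ab[1])]]
    gb <- unit_genes[[which(units$unit_id == ab[2])]]
    anchor_rows[[bi]] <- data.frame(block = bi, gene_a = ga, gene_b = gb,
                                    stringsAsFactors = FALSE)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  }
  for (dp_i in plan$disp_pairs) {
    ga <- unit_genes[[which(units$unit_id == dp_i[1])]]
    gb <- unit_genes[[which(units$unit_id == dp_i[2])]]
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  }
  true_pairs <- do.call(rbind, pair_rows)
  true_blocks <- do.call(rbind, anchor_rows)

  # ---- architectures ------------------------------------------------------
  cat <- cfg$architecture_catalog
  arch_idx <- rep(seq_len(nrow(cat)), cat$count)
  arch_idx <- sample(arch_idx)   # which catalog row each NBS gene gets
  nbs_ids_sorted <- sort(nbs_ids)
  arch_of <- setNames(arch_idx, nbs_ids_sorted)
  subclass_of <- setNames(cat$subclass[arch_idx], nbs_ids_sorted)

  domain_rows <- list()
  hint_rows <- list()
  dom_len <- c(TIR = 150L, CC = 60L, RPW8 = 110L, NBS = 280L, LRR = 220L)
  for (g in nbs_ids_sorted) {
    doms <- strsplit(cat$domains[arch_of[[g]]], ",", fixed = TRUE)[[1]]
    lens <- ifelse(doms %in% names(dom_len), dom_len[doms], 100L)
    ends <- cumsum(lens + 10L)
    starts <- ends - lens + 1L
    domain_rows[[g]] <- data.frame(
      query_id = g, target = doms,
      evalue = 10^-runif(length(doms), 10, 50),
      score = round(runif(length(doms), 50, 300), 1),
      q_start = as.integer(starts), q_end = as.integer(ends),
      source = "cdd", stringsAsFactors = FALSE)
    if (cat$needs_hint[arch_of[[g]]])
      hint_rows[[g]] <- data.frame(gene_id = g, subclass = cat$subclass[arch_of[[g]]],
                                   stringsAsFactors = FALSE)
  }
  domain_hits <- do.call(rbind, domain_rows)
  rownames(domain_hits) <- NULL
  hints <- if (length(hint_rows)) do.call(rbind, hint_rows)
  else data.frame(gene_id = character(), subclass = character())
  rownames(hints) <- NULL

  # ---- candidate-search hit tables ---------------------------------------
  bg_ids <- setdiff(genes$gene_id, nbs_ids)
  decoys <- sort(sample(bg_ids, cfg$decoy_count))
  in_hmm <- runif(length(nbs_ids_sorted)) < 0.85
  in_blast <- runif(length(nbs_ids_sorted)) < 0.85
  in_blast[!in_hmm] <- TRUE  # every true gene is found by at least one search
  mk_hmm <- function(ids, ev) data.frame(
    query_id = ids, target = "NB-ARC", evalue = ev,
    score = round(runif(length(ids), 30, 400), 1),
    q_start = 1L, q_end = 280L, source = "hmm", stringsAsFactors = FALSE)
  hmm_hits <- mk_hmm(c(nbs_ids_sorted[in_hmm], decoys),
                     c(10^-runif(sum(in_hmm), 10, 60),
                       runif(length(decoys), 0.01, 0.9)))
  blast_ids <- c(nbs_ids_sorted[in_blast], decoys)
  blast_hits <- data.frame(
    query_id = blast_ids, target = "NB-ARC_consensus",
    evalue = c(10^-runif(sum(in_blast), 10, 60),
               runif(length(decoys), 0.01, 0.9)),
    score = round(runif(length(blast_ids), 30, 400), 1),
    q_start = 1L, q_end = 280L, source = "blast", stringsAsFactors = FALSE)
  rescan_hits <- mk_hmm(
    c(nbs_ids_sorted, decoys),
    c(10^-runif(length(nbs_ids_sorted), 5, 60),
      runif(length(decoys), cfg$decoy_evalue_range[1], cfg$decoy_evalue_range[2])))

  # ---- all-vs-all similarity ---------------------------------------------
  mk_blast12 <- function(q, s, ev, bits) data.frame(
    query_id = q, target = s, evalue = ev, score = bits,
    q_start = 1L, q_end = 300L, source = "blast", stringsAsFactors = FALSE)
  allvall <- rbind(
    mk_blast12(nbs_ids_sorted, nbs_ids_sorted, 0, 999),
    mk_blast12(true_pairs$gene_a, true_pairs$gene_b,
               10^-runif(nrow(true_pairs), 40, 120),
               round(runif(nrow(true_pairs), 300, 900), 1)),
    mk_blast12(true_pairs$gene_b, true_pairs$gene_a,
               10^-runif(nrow(true_pairs), 40, 120),
               round(runif(nrow(true_pairs), 300, 900), 1)),
    # weak similarities among random background genes, above the paralog
    # E-value ceiling, which downstream filtering must discard
    mk_blast12(sample(bg_ids, 10), sample(bg_ids, 10),
               10^-runif(10, 4, 9), round(runif(10, 40, 60), 1)))

  # ---- ground truth -------------------------------------------------------
  cluster_id_of <- setNames(rep(NA_integer_, length(nbs_ids)), nbs_ids)
  for (ui in seq_len(nrow(units)))
    if (units$clustered[ui])
      cluster_id_of[unit_genes[[ui]]] <- units$cluster_id[ui]
  per_chrom <- table(factor(genes$chrom[match(nbs_ids, genes$gene_id)],
                            levels = chromosomes$chrom))
  truth <- list(
    nbs_ids = nbs_ids_sorted,
    decoys = decoys,
    subclass = subclass_of,
    arch_domains = setNames(cat$domains[arch_of], nbs_ids_sorted),
    subclass_counts = table(factor(subclass_of, levels = c("CNL", "TNL", "RNL"))),
    arch_group_counts = stats::aggregate(
      count ~ subclass + domains, data = cbind(cat[arch_idx, c("subclass", "domains")],
                                               count = 1L), FUN = sum),
    cluster_id = cluster_id_of,
    n_clusters = length(plan$cluster_sizes),
    cluster_sizes = as.integer(plan$cluster_sizes),
    n_singleton_loci = length(nbs_ids) - sum(!is.na(cluster_id_of)),
    per_chromosome_nbs = as.integer(per_chrom),
    dup_label = dup_label[nbs_ids_sorted],
    dup_counts = table(factor(dup_label[nbs_ids_sorted],
                              levels = c("wgd_segmental", "tandem",
                                         "proximal", "dispersed", "singleton"))),
    pairs = true_pairs,
    blocks = true_blocks)
  list(genes = genes, chromosomes = chromosomes,
       hmm_hits = hmm_hits, blast_hits = blast_hits,
       rescan_hits = rescan_hits, domain_hits = domain_hits,
       hints = hints, allvall = allvall, truth = truth)
}

# ---- birth-death gene-tree simulation --------------------------------------

# Species tree as nested list used by the simulator.
species_tree_spec <- function(plan) {
  bl <- plan$branch_lengths
  list(len = NA_real_, children = list(
    list(name = "NcNt", len = bl[["NcNt"]], children = list(
      list(name = "Nc", len = bl[["Nc"]], children = NULL),
      list(name = "Nt", len = bl[["Nt"]], children = NULL))),
    list(name = "Ef", len = bl[["Ef"]], children = NULL)))
}

#' Simulate a species-tagged gene tree by birth-death along a species tree
#'
#' Plants `K` independent gene copies at the root of the ingroup species
#' tree `((Nc,Nt),Ef)`; each copy then evolves down the species tree with
#' per-lineage duplication rate `birth` and loss rate `death`. Tip labels
#' are `<species>_<subclass><lineage>_<n>`; internal nodes carry support
#' values drawn from `support_range`. An optional expansion plan grafts a
#' pure-birth burst of extra copies of one species into one lineage of a
#' given subclass. An outgroup tip is attached at the root. Lineages that
#' lose all tips are recorded as lost (the tree is still returned;
#' regeneration is the caller's choice via the seed).
#'
#' @param cfg A `SimulationConfig`; only `seed` and `tree_plan` are used.
#' @return List with `newick` (string), `stree` (parsed, see
#'   [read_tree()]), `subclass_map` (named vector tip -> subclass) and
#'   `truth` (list: `K`, `surviving`, `per_lineage` data.frame,
#'   `expansion`).
#' @export
simulate_gene_tree <- function(cfg) {
  plan <- cfg$tree_plan
  set.seed(cfg$seed + 1L)
  sp_root <- species_tree_spec(plan)
  counter <- new.env()
  counter$n <- 0L
  supp <- function() round(runif(1, plan$support_range[1], plan$support_range[2]))

  evolve_branch <- function(remaining, lineage_tag, sp_node) {
    # one gene lineage travelling down one species-tree branch
    rate <- plan$birth + plan$death
    wait <- if (rate > 0) rexp(1, rate) else Inf
    if (wait >= remaining) return(at_node(lineage_tag, sp_node))
    if (runif(1) < plan$birth / rate) {
      a <- evolve_branch(remaining - wait, lineage_tag, sp_node)
      b <- evolve_branch(remaining - wait, lineage_tag, sp_node)
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      merge_nodes(a, b)
    } else NULL
  }
  at_node <- function(lineage_tag, sp_node) {
    if (is.null(sp_node$children)) {
      counter$n <- counter$n + 1L
      lab <- sprintf("%s_%s_%d", sp_node$name, lineage_tag, counter$n)
      return(list(nwk = paste0(lab, ":1"), tips = setNames(1L, sp_node$name),
                  labels = lab))
    }
    kids <- lapply(sp_node$children, function(ch)
      evolve_branch(ch$len, lineage_tag, ch))
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    Reduce(merge_nodes, kids)
  }
  merge_nodes <- function(a, b) {
    tips <- c(a$tips, b$tips)
    tips <- tapply(tips, names(tips), sum)
    list(nwk = sprintf("(%s,%s)%d:1", a$nwk, b$nwk, supp()),
         tips = tips, labels = c(a$labels, b$labels))
  }

  split <- plan$subclass_split
  lineage_sub <- rep(names(split), split)
  stopifnot(length(lineage_sub) == plan$K)
  lineages <- vector("list", plan$K)
  for (k in seq_len(plan$K)) {
    tag <- sprintf("%s%03d", substr(lineage_sub[k], 1, 1), k)
    lineages[[k]] <- evolve_branch(0, tag, sp_root)  # enter root node directly
  }

  # expansion burst: extra same-species copies inside one surviving lineage
  expansion <- NULL
  if (!is.null(plan$expansion) && plan$expansion$size > 0L) {
    sp <- plan$expansion$species
    cand <- which(vapply(seq_len(plan$K), function(k) {
      !is.null(lineages[[k]]) && lineage_sub[k] == plan$expansion$subclass &&
        sp %in% names(lineages[[k]]$tips)
    }, logical(1)))
    if (length(cand)) {
      k <- cand[1]
      tag <- sprintf("%s%03d", substr(lineage_sub[k], 1, 1), k)
      victim <- grep(paste0("^", sp, "_"), lineages[[k]]$labels, value = TRUE)[1]
      extra <- vapply(seq_len(plan$expansion$size - 1L), function(i) {
        counter$n <- counter$n + 1L
        sprintf("%s_%s_%d", sp, tag, counter$n)
      }, character(1))
      burst <- paste0(victim, ":1")
      for (e in extra) burst <- sprintf("(%s,%s:1)%d:0.1", burst, e, supp())
      lin <- lineages[[k]]
      lin$nwk <- sub(paste0(victim, ":1"), burst, lin$nwk, fixed = TRUE)
      lin$labels <- c(lin$labels, extra)
      lin$tips[sp] <- lin$tips[sp] + length(extra)
      lineages[[k]] <- lin
      expansion <- list(lineage = k, species = sp,
                        size = plan$expansion$size,
                        subclass = plan$expansion$subclass)
    }
  }

  alive <- which(!vapply(lineages, is.null, logical(1)))
  if (!length(alive))
    nbs_stop("all gene lineages were lost; use a different seed or lower the loss rate",
             "nbsurvey_simulation_error")
  inner <- if (length(alive) == 1L) lineages[[alive]]$nwk
  else sprintf("(%s)%d:1",
               paste(vapply(alive, function(k) lineages[[k]]$nwk, character(1)),
                     collapse = ","), supp())
  newick <- sprintf("(%s,%s_out1:3);", inner, plan$outgroup)
  stree <- species_tree_labels(ape::read.tree(text = newick))
  subclass_map <- unlist(lapply(seq_len(plan$K), function(k) {
    if (is.null(lineages[[k]])) return(NULL)
    setNames(rep(lineage_sub[k], length(lineages[[k]]$labels)),
             lineages[[k]]$labels)
  }))
  per_lineage <- do.call(rbind, lapply(seq_len(plan$K), function(k) {
    tips <- if (is.null(lineages[[k]])) integer(0) else lineages[[k]]$tips
    counts <- vapply(plan$ingroup, function(s)
      as.integer(if (s %in% names(tips)) tips[[s]] else 0L), integer(1))
    data.frame(lineage = k, subclass = lineage_sub[k],
               t(counts), stringsAsFactors = FALSE)
  }))
  names(per_lineage)[-(1:2)] <- plan$ingroup
  surviving <- sum(rowSums(per_lineage[plan$ingroup]) > 0L)
  list(newick = newick, stree = stree, subclass_map = subclass_map,
       truth = list(K = plan$K, surviving = surviving,
                    per_lineage = per_lineage,
                    surviving_per_subclass = table(
                      per_lineage$subclass[rowSums(per_lineage[plan$ingroup]) > 0L]),
                    inherited = vapply(plan$ingroup, function(s)
                      sum(per_lineage[[s]] > 0L), integer(1)),
                    expansion = expansion))
}

#' Simulate a gene x sample expression matrix with planted regimes
#'
#' Each family gene is assigned a `low` regime with probability
#' `frac_low` (exponential abundances around `low_mean` TPM) or an
#' `expressed` regime (gamma abundances around `expressed_mean` TPM);
#' decoys get expressed-regime values. The realized level (mean against
#' `low_threshold`) is recorded alongside the intended regime.
#'
#' @param cfg A `SimulationConfig`.
#' @param nbs_ids Family gene ids.
#' @param decoys Decoy gene ids (optional).
#' @return List with `matrix` and `truth` (data.frame `gene_id`,
#'   `regime`, `level`).
#' @export
simulate_expression <- function(cfg, nbs_ids, decoys = character(0)) {
  ex <- cfg$expression
  set.seed(cfg$seed + 2L)
  ids <- c(nbs_ids, decoys)
  regime <- c(ifelse(runif(length(nbs_ids)) < ex$frac_low, "low", "expressed"),
              rep("expressed", length(decoys)))
  m <- t(vapply(regime, function(r) {
    if (r == "low") rexp(ex$n_samples, rate = 1 / ex$low_mean)
    else rgamma(ex$n_samples, shape = 2, scale = ex$expressed_mean / 2)
  }, numeric(ex$n_samples)))
  m <- round(m, 3)
  rownames(m) <- ids
  colnames(m) <- sprintf("sample%d", seq_len(ex$n_samples))
  truth <- data.frame(gene_id = ids, regime = regime,
                      level = ifelse(rowMeans(m) < ex$low_threshold,
                                     "low", "expressed"),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(matrix = m, truth = truth)
}

#' Simulate a complete survey fixture set on disk
#'
#' Runs [simulate_genome()], [simulate_gene_tree()] and
#' [simulate_expression()] and writes `genome.gff3`, `hmm_hits.tsv`,
#' `blast_hits.tsv`, `rescan_hits.tsv`, `domain_hits.tsv`,
#' `subclass_hints.tsv`, `allvall.tsv`, `chromosomes.tsv`, `tree.nwk`,
#' `tree_subclasses.tsv`, `expr.tsv` and `truth.json` into `dir`.
#' Identical configurations and seeds give byte-identical files.
#'
#' @param cfg A `SimulationConfig`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of simulated objects (`genome`, `tree`,
#'   `expression`, `paths`).
#' @export
simulate_survey <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(cfg)
  tre <- simulate_gene_tree(cfg)
  expr <- simulate_expression(cfg, gen$truth$nbs_ids, gen$truth$decoys)
  p <- function(f) file.path(dir, f)
  write_gff(gen$genes, p("genome.gff3"))
  write_hit_table(gen$hmm_hits, p("hmm_hits.tsv"))
  write_blast12(gen$blast_hits, p("blast_hits.tsv"))
  write_hit_table(gen$rescan_hits, p("rescan_hits.tsv"))
  write_hit_table(gen$domain_hits, p("domain_hits.tsv"))
  write.table(gen$hints, p("subclass_hints.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_blast12(gen$allvall, p("allvall.tsv"))
  write.table(gen$chromosomes, p("chromosomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(tre$newick, p("tree.nwk"))
  write.table(data.frame(gene_id = names(tre$subclass_map),
                         subclass = unname(tre$subclass_map)),
              p("tree_subclasses.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_expression(expr$matrix, p("expr.tsv"))
  truth <- c(gen$truth,
             list(tree = tre$truth, expression = expr$truth))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(genome = gen, tree = tre, expression = expr,
                 paths = vapply(c("genome.gff3", "hmm_hits.tsv",
                                  "blast_hits.tsv", "rescan_hits.tsv",
                                  "domain_hits.tsv", "subclass_hints.tsv",
                                  "allvall.tsv", "chromosomes.tsv",
                                  "tree.nwk", "tree_subclasses.tsv",
                                  "expr.tsv", "truth.json"), p, character(1))))
}

# 12-column BLAST outfmt-6 writer for hit tables carrying the package's
# canonical columns.
write_blast12 <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(hits$query_id, hits$target,
                   rep(95.0, n), rep(300L, n), rep(5L, n), rep(0L, n),
                   hits$q_start, hits$q_end, hits$q_start, hits$q_end,
                   hits$evalue, hits$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
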