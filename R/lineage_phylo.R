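# Default ingroup species tree used for LCA mapping: E. ferox sister to
# the two Nymphaea species.
DEFAULT_SPECIES_TREE <- "((Nc,Nt),Ef);"

# children list per node of a phylo tree (index = node number)
phylo_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}

#' Collapse poorly supported branches into multifurcations
#'
#' Internal edges whose child node carries a support value below
#' `min_support` are contracted (the child's children are spliced into its
#' parent, branch lengths added through). Missing supports are treated as
#' at or above the threshold. Tips are never removed.
#'
#' @param stree Species-tagged tree list from [read_tree()].
#' @param min_support Support threshold (default 50, the usual UFBoot
#'   floor for a retained bipartition).
#' @return A species-tagged tree list with low-support edges contracted.
#' @export
collapse_low_support <- function(stree, min_support = 50) {
  tree <- stree$tree
  ntip <- ape::Ntip(tree)
  if (tree$Nnode <= 1L) return(stree)
  support <- stree$support
  if (is.null(support)) support <- rep(NA_real_, tree$Nnode)
  rt <- root_node(tree)
  # node numbers (ntip+1 ..) of internal nodes to contract; never the root
  weak <- which(!is.na(support) & support < min_support) + ntip
  weak <- setdiff(weak, rt)
  if (!length(weak)) return(stree)
  kids <- phylo_children(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  alive <- rep(TRUE, ntip + tree$Nnode)
  # process bottom-up so chains of weak nodes collapse fully
  for (w in sort(weak, decreasing = TRUE)) {
    p <- parent[w]
    for (ch in kids[[w]]) {
      parent[ch] <- p
      if (!is.na(elen[ch]) && !is.na(elen[w])) elen[ch] <- elen[ch] + elen[w]
    }
    kids[[p]] <- c(setdiff(kids[[p]], w), kids[[w]])
    alive[w] <- FALSE
  }
  # rebuild a phylo via a newick string (keeps supports of surviving nodes)
  supp_of <- function(nd) support[nd - ntip]
  build <- function(nd) {
    if (nd <= ntip) {
      lab <- tree$tip.label[nd]
    } else {
      sub <- vapply(kids[[nd]], build, character(1))
      s <- supp_of(nd)
      lab <- paste0("(", paste(sub, collapse = ","), ")",
                    if (!is.na(s)) format(s, trim = TRUE) else "")
    }
    if (!is.na(elen[nd])) paste0(lab, ":", format(elen[nd], trim = TRUE,
                                                  scientific = FALSE))
    else lab
  }
  nwk <- paste0(build(rt), ";")
  out <- ape::read.tree(text = nwk)
  species_tree_labels(out, species_delim = attr(stree, "delim") %||% "_")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconcile a gene tree against its species content (species overlap)
#'
#' Labels every internal node of a rooted, species-tagged gene tree as a
#' duplication or a speciation by the species-overlap criterion: a node is
#' a duplication when at least two of its children subtend intersecting
#' ingroup species sets. Nodes with fewer than two ingroup-bearing
#' children are pass-through (`leaf-parent`). Outgroup tips are excluded
#' from all species sets (they serve rooting only).
#'
#' @param stree Species-tagged tree list from [read_tree()].
#' @param ingroup_species Character vector of ingroup species tags.
#' @return A `ReconciledTree` list: `tree`, `species`, `support`,
#'   `ingroup`, `node_species` (list of ingroup species sets per node),
#'   `node_event` (per node; `NA` for tips), `n_ingroup_tips` (per node).
#' @export
reconcile <- function(stree, ingroup_species) {
  tree <- stree$tree
  ntip <- ape::Ntip(tree)
  tipsp <- unname(stree$species[tree$tip.label])
  if (!any(tipsp %in% ingroup_species))
    nbs_stop("no ingroup tips in tree", "nbsurvey_empty_reconciliation_error")
  n_all <- ntip + tree$Nnode
  kids <- phylo_children(tree)
  spset <- vector("list", n_all)
  ntips_in <- integer(n_all)
  event <- rep(NA_character_, n_all)
  for (i in seq_len(ntip)) {
    spset[[i]] <- if (tipsp[i] %in% ingroup_species) tipsp[i] else character(0)
    ntips_in[i] <- length(spset[[i]])
  }
  ord <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (nd in ord) {
    ch <- kids[[nd]]
    spset[[nd]] <- sort(unique(unlist(spset[ch])))
    ntips_in[nd] <- sum(ntips_in[ch])
    bearing <- ch[vapply(spset[ch], length, integer(1)) > 0L]
    if (length(bearing) < 2L) {
      event[nd] <- "leaf-parent"
    } else {
      sets <- spset[bearing]
      dup <- FALSE
      for (a in seq_along(sets)[-length(sets)])
        for (b in seq((a + 1L), length(sets)))
          if (length(intersect(sets[[a]], sets[[b]]))) { dup <- TRUE; break }
      event[nd] <- if (dup) "duplication" else "speciation"
    }
  }
  structure(list(tree = tree, species = stree$species,
                 support = stree$support, ingroup = ingroup_species,
                 node_species = spset, node_event = event,
                 n_ingroup_tips = ntips_in),
            class = "nbs_reconciled")
}

# MRCA node of a species set in a species tree; NA for empty sets.
species_mrca <- function(sp_tree, species_set) {
  if (!length(species_set)) return(NA_integer_)
  tips <- match(species_set, sp_tree$tip.label)
  if (anyNA(tips))
    nbs_stop(sprintf("species not in species tree: %s",
                     paste(species_set[is.na(tips)], collapse = ", ")),
             "nbsurvey_validation_error")
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(sp_tree, tips)
}

#' Count ancestral lineages at the ingroup root
#'
#' An ancestral lineage is a gene copy present in the common ancestor of
#' the ingroup species. Operationally, every duplication node whose
#' ingroup species set maps (by LCA) to the root of the ingroup species
#' tree represents a duplication in or above that ancestor, so the edges
#' to its children are cut; the maximal subtrees that remain, restricted
#' to those containing at least one ingroup tip, are the ancestral
#' lineages. Losses can only merge copies out of view, so the count is a
#' lower bound on the true ancestral copy number.
#'
#' @param rec A `ReconciledTree` from [reconcile()].
#' @param species_tree Newick string (or `ape::phylo`) of the ingroup
#'   species tree; default `"((Nc,Nt),Ef);"`.
#' @param subclass_map Optional named character vector tip label ->
#'   subclass (`TNL`/`CNL`/`RNL`); when given, each lineage is assigned
#'   the majority subclass of its tips (ties are an error, as subclasses
#'   are expected to be monophyletic).
#' @return An `AncestralLineageReport` list: `lineages` (data.frame with
#'   `lineage_id`, `subclass`, one `n_<species>` column per ingroup
#'   species and `n_total`), `total`, `per_subclass` (table or `NULL`),
#'   `inherited` (named vector per species), `tip_lineage` (named vector
#'   tip label -> lineage id, ingroup tips only).
#' @export
count_ancestral_lineages <- function(rec, species_tree = DEFAULT_SPECIES_TREE,
                                     subclass_map = NULL) {
  stopifnot(inherits(rec, "nbs_reconciled"))
  sp_tree <- if (inherits(species_tree, "phylo")) species_tree
  else ape::read.tree(text = species_tree)
  sp_tree <- ape::keep.tip(sp_tree, intersect(sp_tree$tip.label, rec$ingroup))
  sp_root <- root_node(sp_tree)
  tree <- rec$tree
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  cut_node <- vapply(seq_len(n_all), function(nd) {
    !is.na(rec$node_event[nd]) && rec$node_event[nd] == "duplication" &&
      identical(species_mrca(sp_tree, rec$node_species[[nd]]), sp_root)
  }, logical(1))
  kids <- phylo_children(tree)
  rt <- root_node(tree)
  lineage_of <- integer(n_all)
  next_id <- 0L
  # preorder walk: children of a cut node start fresh lineages
  stack <- rt
  lineage_of[rt] <- if (cut_node[rt]) 0L else { next_id <- 1L; 1L }
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in kids[[nd]]) {
      if (cut_node[nd]) {
        next_id <- next_id + 1L
        lineage_of[ch] <- next_id
      } else lineage_of[ch] <- lineage_of[nd]
      if (ch > ntip) stack <- c(stack, ch)
    }
  }
  tip_in <- which(unname(rec$species[tree$tip.label]) %in% rec$ingroup)
  tipsp <- unname(rec$species[tree$tip.label])
  lin_ids <- sort(unique(lineage_of[tip_in]))
  lin_ids <- lin_ids[lin_ids > 0L]
  rows <- lapply(seq_along(lin_ids), function(i) {
    tips <- tip_in[lineage_of[tip_in] == lin_ids[i]]
    counts <- vapply(rec$ingroup, function(s) sum(tipsp[tips] == s), integer(1))
    sub <- NA_character_
    if (!is.null(subclass_map)) {
      sc <- subclass_map[tree$tip.label[tips]]
      sc <- sc[!is.na(sc)]
      if (length(sc)) {
        tb <- sort(table(sc), decreasing = TRUE)
        if (length(tb) > 1L && tb[1] == tb[2])
          nbs_stop(sprintf("subclass tie in lineage %d", i),
                   "nbsurvey_validation_error")
        sub <- names(tb)[1]
      }
    }
    c(list(lineage_id = sprintf("A%03d", i), subclass = sub),
      as.list(setNames(counts, paste0("n_", rec$ingroup))),
      list(n_total = length(tips)))
  })
  lineages <- do.call(rbind, lapply(rows, as.data.frame))
  tip_lineage <- setNames(
    sprintf("A%03d", match(lineage_of[tip_in], lin_ids)),
    tree$tip.label[tip_in])
  inherited <- vapply(rec$ingroup, function(s)
    sum(lineages[[paste0("n_", s)]] > 0L), integer(1))
  per_subclass <- if (!is.null(subclass_map))
    table(lineages$subclass) else NULL
  list(lineages = lineages,
       total = nrow(lineages),
       per_subclass = per_subclass,
       inherited = inherited,
       tip_lineage = tip_lineage)
}

#' Find lineage-specific expansions
#'
#' Reports every (lineage, species) combination whose tip count reaches
#' `min_size`, sorted by descending count — the signature of a burst of
#' species-specific duplication inside one ancestral lineage.
#'
#' @param report Output of [count_ancestral_lineages()].
#' @param min_size Minimum per-species tip count (default 10).
#' @return `data.frame` with `lineage_id`, `species`, `count`.
#' @export
detect_expansions <- function(report, min_size = 10) {
  lin <- report$lineages
  sp <- sub("^n_", "", grep("^n_(?!total)", names(lin), perl = TRUE, value = TRUE))
  rows <- do.call(rbind, lapply(sp, function(s)
    data.frame(lineage_id = lin$lineage_id, species = s,
               count = lin[[paste0("n_", s)]], stringsAsFactors = FALSE)))
  rows <- rows[rows$count >= min_size, , drop = FALSE]
  rows <- rows[order(-rows$count, rows$lineage_id, rows$species), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
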