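# Canonical NLR domain vocabulary and their one-letter codes used in
# architecture strings.  Any other domain name is treated as an integrated
# domain (ID).
CANONICAL_DOMAINS <- c(TIR = "T", CC = "C", RPW8 = "R", NBS = "N", LRR = "L")

#' Merge the two permissive candidate searches
#'
#' The family is first searched two ways at a permissive threshold
#' (E <= 1.0): a profile-HMM search with the NB-ARC domain model and a
#' BLASTp search with the same domain sequence. Candidates are the union
#' of query ids over both hit tables, deduplicated.
#'
#' @param hmm_hits,blast_hits Hit tables (see [read_hit_table()]); either
#'   may be empty.
#' @param evalue_max Permissive threshold applied to both tables
#'   (default 1.0).
#' @return Character vector of unique candidate gene ids, sorted.
#' @export
merge_candidates <- function(hmm_hits, blast_hits, evalue_max = 1.0) {
  ids <- c(hmm_hits$query_id[hmm_hits$evalue <= evalue_max],
           blast_hits$query_id[blast_hits$evalue <= evalue_max])
  sort(unique(ids))
}

#' Confirm candidates by a strict NB-ARC re-scan
#'
#' Candidates are kept only if a re-scan of their protein against the
#' NB-ARC model produces at least one hit at or below the strict threshold
#' (default E = 1e-4). Re-scan hits for non-candidate ids are ignored with
#' a warning.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param rescan_hits Hit table of NB-ARC re-scan hits.
#' @param threshold Strict E-value cutoff (default `1e-4`).
#' @return Character vector of confirmed NBS gene ids (subset of
#'   `candidates`), sorted.
#' @export
strict_rescan_filter <- function(candidates, rescan_hits, threshold = 1e-4) {
  unknown <- setdiff(unique(rescan_hits$query_id), candidates)
  if (length(unknown))
    warning(sprintf("ignoring re-scan hits for %d non-candidate id(s)",
                    length(unknown)))
  keep <- rescan_hits$query_id %in% candidates &
    rescan_hits$evalue <= threshold
  sort(intersect(candidates, unique(rescan_hits$query_id[keep])))
}

#' Build ordered per-gene domain annotations from domain hit tables
#'
#' Collapses raw per-residue domain hits (CDD-style) into one ordered
#' segment list per gene: segments are sorted by query start; overlapping
#' segments of the same domain are merged by interval union; where
#' segments of different domains overlap, the lower-E-value one wins.
#'
#' @param domain_hits Hit table whose `target` column carries domain names
#'   (`TIR`, `CC`, `RPW8`, `NBS`, `LRR`, or any integrated-domain name).
#' @return Named list (by gene id) of data.frames with columns `domain`,
#'   `q_start`, `q_end`, `evalue`, `source`.
#' @export
build_domain_annotations <- function(domain_hits) {
  split_hits <- split(domain_hits, domain_hits$query_id)
  lapply(split_hits, function(h) {
    h <- h[order(h$q_start, h$q_end), , drop = FALSE]
    segs <- list()
    for (i in seq_len(nrow(h))) {
      merged <- FALSE
      if (length(segs)) {
        last <- segs[[length(segs)]]
        if (last$domain == h$target[i] && h$q_start[i] <= last$q_end + 1L) {
          last$q_end <- max(last$q_end, h$q_end[i])
          last$evalue <- min(last$evalue, h$evalue[i])
          segs[[length(segs)]] <- last
          merged <- TRUE
        } else if (last$domain != h$target[i] && h$q_start[i] <= last$q_end) {
          # conflicting-name overlap: keep the lower E-value segment
          if (h$evalue[i] < last$evalue) {
            segs[[length(segs)]] <- list(domain = h$target[i],
                                         q_start = h$q_start[i],
                                         q_end = h$q_end[i],
                                         evalue = h$evalue[i],
                                         source = h$source[i])
          }
          merged <- TRUE
        }
      }
      if (!merged)
        segs[[length(segs) + 1L]] <- list(domain = h$target[i],
                                          q_start = h$q_start[i],
                                          q_end = h$q_end[i],
                                          evalue = h$evalue[i],
                                          source = h$source[i])
    }
    out <- do.call(rbind, lapply(segs, as.data.frame))
    names(out)[1] <- "domain"
    out
  })
}

#' Classify the domain architecture of one gene
#'
#' The subclass follows the N-terminal domain preceding the first NBS
#' segment: RPW8 gives RNL, TIR gives TNL, CC gives CNL (precedence
#' RPW8 > TIR > CC when several co-occur). Genes whose NBS is not preceded
#' by any canonical N-terminal domain are `NL-ambiguous` unless a
#' `profile_subclass` hint (e.g. best-matching reference family from a
#' BLAST against curated NLR sets) resolves them. The architecture string
#' concatenates canonical one-letter codes in positional order with
#' repeats preserved (`RNRN`); non-canonical domains are recorded as
#' integrated domains with an N/C terminus flag and rendered as
#' `name(N)-`/`-name(C)` affixes.
#'
#' @param annot One element of [build_domain_annotations()] output.
#' @param gene_id Gene identifier.
#' @param profile_subclass Optional subclass hint (`"TNL"`, `"CNL"`,
#'   `"RNL"`) used only when no canonical N-terminal domain is present.
#' @return A list with `gene_id`, `arch_string`, `subclass`, `intact`,
#'   `integrated_domains` (data.frame `name`, `terminus`).
#' @export
classify_architecture <- function(annot, gene_id = "gene",
                                  profile_subclass = NULL) {
  if (!any(annot$domain == "NBS"))
    nbs_stop(sprintf("gene %s has no NBS segment", gene_id),
             "nbsurvey_precondition_error")
  annot <- annot[order(annot$q_start, annot$q_end), , drop = FALSE]
  first_nbs <- min(which(annot$domain == "NBS"))
  nterm <- annot$domain[seq_len(first_nbs - 1L)]
  subclass <- if ("RPW8" %in% nterm) "RNL"
  else if ("TIR" %in% nterm) "TNL"
  else if ("CC" %in% nterm) "CNL"
  else if (!is.null(profile_subclass)) match.arg(profile_subclass,
                                                 c("TNL", "CNL", "RNL"))
  else "NL-ambiguous"

  canonical <- annot$domain %in% names(CANONICAL_DOMAINS)
  arch <- paste(CANONICAL_DOMAINS[annot$domain[canonical]], collapse = "")

  ids <- annot[!canonical, , drop = FALSE]
  terminus <- character(0)
  if (nrow(ids)) {
    nbs_start <- annot$q_start[first_nbs]
    terminus <- ifelse(ids$q_end < nbs_start, "N", "C")
    pre <- ids$domain[terminus == "N"]
    post <- ids$domain[terminus == "C"]
    if (length(pre)) arch <- paste0(paste0(pre, "(N)", collapse = "-"), "-", arch)
    if (length(post)) arch <- paste0(arch, "-", paste0(post, "(C)", collapse = "-"))
  }

  nterm_letter <- c(TNL = "TIR", CNL = "CC", RNL = "RPW8")[subclass]
  intact <- !is.na(nterm_letter) &&
    nterm_letter %in% annot$domain && "LRR" %in% annot$domain
  list(gene_id = gene_id,
       arch_string = arch,
       subclass = subclass,
       intact = isTRUE(intact),
       integrated_domains = data.frame(name = ids$domain,
                                       terminus = terminus,
                                       stringsAsFactors = FALSE))
}

#' Classify architectures for a whole cohort
#'
#' @param annotations Output of [build_domain_annotations()].
#' @param gene_ids Which genes to classify (default: all annotated).
#' @param hints Optional named character vector gene id -> subclass hint.
#' @return A `data.frame` with one row per gene: `gene_id`, `subclass`,
#'   `arch_string`, `intact`, `integrated_domains` (comma-joined
#'   `name:terminus` or `""`).
#' @export
classify_architectures <- function(annotations, gene_ids = names(annotations),
                                   hints = NULL) {
  missing <- setdiff(gene_ids, names(annotations))
  if (length(missing))
    nbs_stop(sprintf("no domain annotation for gene(s): %s",
                     paste(head(missing, 5), collapse = ", ")),
             "nbsurvey_validation_error")
  rows <- lapply(gene_ids, function(g) {
    call <- classify_architecture(annotations[[g]], g,
                                  profile_subclass = if (!is.null(hints)) unname(hints[g]) else NULL)
    idstr <- if (nrow(call$integrated_domains))
      paste(paste0(call$integrated_domains$name, ":",
                   call$integrated_domains$terminus), collapse = ",")
    else ""
    data.frame(gene_id = call$gene_id, subclass = call$subclass,
               arch_string = call$arch_string, intact = call$intact,
               integrated_domains = idstr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate architecture groups per subclass
#'
#' One row per distinct (subclass, architecture) combination with its
#' count and its percentage within the subclass (one decimal place, as
#' conventionally reported).
#'
#' @param calls Output of [classify_architectures()].
#' @return `data.frame` with `subclass`, `arch_string`, `count`,
#'   `percent`.
#' @export
summarize_architecture_groups <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(subclass = character(), arch_string = character(),
                      count = integer(), percent = numeric()))
  tab <- as.data.frame(table(subclass = calls$subclass,
                             arch_string = calls$arch_string),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3] <- "count"
  totals <- tapply(tab$count, tab$subclass, sum)
  tab$percent <- round(100 * tab$count / as.numeric(totals[tab$subclass]), 1)
  tab <- tab[order(tab$subclass, -tab$count, tab$arch_string), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
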