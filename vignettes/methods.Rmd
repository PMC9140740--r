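---
title: "Methods: surveying an NBS-LRR gene family with nbsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying an NBS-LRR gene family with nbsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind each pipeline stage, the
default parameters and why they were chosen, what the synthetic-data
generator does and does not emulate, and the design decisions a user
should know before trusting the output.

# The survey model

A genome-wide NBS-LRR survey answers five questions about one genome
(and, for the phylogenetic part, a small set of related species):

1. **Which genes are family members?** (identification)
2. **What is each member's domain architecture?** (classification)
3. **How are members arranged along chromosomes?** (clusters and loci)
4. **How did the family expand?** (duplication types; ancestral
   lineages from a gene tree)
5. **Are members expressed at baseline?**

Each stage is a pure function over data frames; `run_pipeline()` only
sequences them and cross-checks the sums.

# Identification

Candidates are the union of two searches — an NB-ARC profile scan and a
protein-similarity search against known NLRs — taken at a deliberately
permissive ceiling, then confirmed by a strict profile re-scan.

| parameter | default | rationale |
|---|---|---|
| `permissive_evalue` | 1.0 | the union stage exists to maximize recall; precision is delegated entirely to the re-scan |
| `strict_evalue` | 1e-4 | conventional domain-presence threshold; separates true NB-ARC domains from spurious weak hits by many orders of magnitude in practice |

The two-stage design makes the survey robust to noisy candidate lists:
adding junk candidates cannot change the confirmed set, a property the
test suite checks directly (decoy genes with re-scan E-values between
1e-3 and 0.5 are always rejected).

# Architecture classification

Domain hits per gene are sorted by position and merged: same-name
overlapping segments are unioned (keeping the best E-value);
different-name overlaps keep the lower-E-value segment. The resulting
N→C domain string determines everything else:

- **Subclass** = first of RPW8/TIR/CC occurring before the first NBS,
  with precedence RPW8 > TIR > CC when several occur. RPW8 wins because
  RNLs are a small, ancient, functionally distinct helper clade and
  their RPW8 domain is diagnostic even when a CC-like signal co-occurs;
  TIR over CC because CC predictions are the least reliable.
- Genes with NBS but no N-terminal domain are `NL-ambiguous` unless a
  **subclass hint** (best-hit assignment against curated
  reference NLR sets, supplied as a two-column TSV) resolves them.
  This mirrors standard practice: truncated N/NL genes are assigned to
  a subclass by similarity, not by their own domains.
- Domains outside {TIR, CC, RPW8, NBS, LRR} become **integrated
  domains**, reported with their terminus, e.g. `TNL-MARCH1(C)` or
  `WRKY(N)-TNL`.
- **Intact** requires N-terminal domain + NBS + LRR.

Architecture-group percentages are displayed with one decimal within a
subclass (e.g. 6 of 18 RNLs intact → 33.3%).

# Cluster calling

Two members on the same chromosome are linked when the gap between
their gene *intervals* is ≤ `window` (default 250 kb, the conventional
flanking distance for resistance-gene clusters); loci are connected
components under this rule (single linkage). The implementation is a
per-chromosome sweep over start-sorted genes maintaining the running
maximum end; a brute-force O(n²) union-find oracle verifies it on
random instances in the test suite and in `scripts/acceptance.R`.

`anchor = "start"` instead measures between start points. The interval
anchor is the default because "upstream and downstream of a gene"
naturally reads as distance from the gene body; the start anchor is
kept because some published surveys use midpoint- or start-based
distances, and on genomes with very long genes the two disagree (a long
gene can bridge neighbours the start rule would split).

Reported totals satisfy `loci = singletons + clusters` and
`genes = singletons + clustered_genes` by construction; the mean
cluster size is stored at full precision and *displayed* rounded to the
nearest integer (87 genes / 18 clusters = 4.83 → "5").

# Duplication typing

Paralog pairs come from an all-vs-all protein search: self-hits
removed, each query keeps its `top_n_hits = 5` best non-self subjects
by bitscore at `paralog_evalue ≤ 1e-10`, pairs deduplicated. These
conventions (top-5, 1e-10) follow the de-facto standard of
collinearity-scanning tools, which cap hits per query so tandem arrays
do not flood the anchor set.

Anchors are expressed in gene-*rank* coordinates (position index along
the chromosome among all genes, not base pairs), because collinearity
is a statement about gene order. Per chromosome pair, dynamic
programming finds the chain maximizing anchor count with strictly
monotone ranks on both axes and rank gaps ≤ `max_gap = 25` on either
axis, in both orientations; chains are removed greedily and reported at
`min_block_size = 5` anchors. Both 25 and 5 are the standard defaults
for syntenic-block detection; the DP is verified against exhaustive
chain enumeration for small anchor sets.

Labels then follow a strict precedence, each gene getting exactly one:

```
wgd_segmental  (anchor in any collinear block)
  > tandem     (paralog at rank distance 1, same chromosome)
  > proximal   (paralog at rank distance 2..20)
  > dispersed  (any remaining paralog)
  > singleton  (no paralog)
```

Segmental evidence wins because a collinear block is corroborated by
the neighbourhood, not just one pair. By default only within-family
pairs count as tandem/proximal/dispersed evidence (`nbs_only = TRUE`),
since the family's own expansion is what is being classified; the full
gene set still defines ranks. Duplication shares are displayed as whole
percents (28 tandem of 131 → "21%").

# Ancestral lineages

The input is a rooted gene tree over the ingroup species (tags `Ef`,
`Nc`, `Nt` by default, species tree `((Nc,Nt),Ef)`) plus an outgroup
used only for rooting. The procedure:

1. **Support collapse.** Branches with support < `min_support = 50`
   (the usual floor for retaining a bootstrap bipartition) are
   contracted into multifurcations, so arbitrary resolutions of
   unsupported splits cannot create or destroy duplications.
2. **Species-overlap reconciliation.** A node is a duplication iff at
   least two of its children subtend intersecting ingroup species
   sets. This needs no branch lengths and is robust on
   multifurcations; outgroup tips carry empty species sets.
3. **Root-mapping cut.** A duplication node whose ingroup species set
   LCA-maps to the *root* of the species tree happened at or before
   the ingroup ancestor. Cutting the child edges of all such nodes
   partitions the tree; components containing at least one ingroup tip
   are the **ancestral lineages** — gene copies already present in the
   common ancestor.

A lineage surviving in only one species still counts once (that is the
point: presence in the ancestor, not in every descendant), and losses
can only merge copies out of view, so the count is a lower bound.
Per-lineage per-species tip counts give the per-species inherited
numbers and expose expansions (`detect_expansions`, default threshold
10 tips of one species in one lineage — large enough that a birth-death
process at realistic rates essentially never reaches it without a
planted burst).

# Expression

A member is "low" when its mean abundance across samples is strictly
below `low_threshold = 1.0` (the conventional TPM floor for calling a
gene expressed). The stage reports the low fraction and a log2(x+1)
matrix for display. No normalization is attempted — the input is
assumed to be an already normalized abundance matrix.

# The synthetic generator

`simulate_survey()` writes a complete input set (GFF3, four hit tables,
hints, all-vs-all table, chromosome table, Newick tree, tree subclass
map, expression matrix) plus `truth.json`. Defaults describe the survey
conditions the pipeline is meant for — they are fixed study conditions,
not tuning knobs:

- 29 chromosomes, ~22,000 genes (600–920 per chromosome, shuffled so
  chromosome length is independent of family content); 131 family
  members (40 CNL / 73 TNL / 18 RNL) over a 24-group architecture
  catalog; 25 decoys whose re-scan E-values fall between the strict and
  permissive thresholds.
- 18 clusters of sizes 10,8,7,7,6,6,5,5,5,4,4,4,4,3,3,2,2,2 (87 genes)
  on three chromosomes, 44 singleton loci elsewhere; one chromosome
  empty, seven carrying exactly one member. Intra-locus neighbours are
  ~30 kb apart; distinct loci are separated by 31 background genes
  (> 250 kb and > 25 ranks), so the planted partition is exactly what
  any correct caller must find.
- Duplication plan 28 tandem / 15 proximal / 18 dispersed / 70
  segmental, the segmental genes arranged as 7 collinear blocks of 5
  anchor pairs across chromosome pairs. Units are packed into clusters
  by a first-fit-decreasing heuristic; an `adversarial = TRUE` mode
  additionally plants rank-adjacent paralog pairs inside one block so
  the precedence rule is actually exercised.
- A birth–death gene tree (duplication 0.2, loss 0.05 per unit branch
  length) with K = 122 copies entering exactly at the ingroup root —
  so within-copy duplications never LCA-map to the root and the
  planted copy count is identifiable — plus a grafted 102-copy CNL
  burst in `Nc` and an outgroup tip. Supports are drawn in [70, 100],
  above the collapse threshold.
- Expression: 70% of members in a low regime (exponential, mean 0.3),
  the rest gamma with mean 20; truth records both the intended regime
  and the realized level.

**What is not emulated:** sequences (all evidence enters as tabular
search results), assembly noise (no split/merged gene models),
overlapping genes, hit-table artifacts beyond decoys and weak
background similarities, incomplete lineage sorting or horizontal
transfer in the gene tree, and read-level expression noise. The
generator validates its own configuration and fails loudly when a plan
is infeasible (e.g. a duplication plan that cannot tile the requested
clusters).

# Reproducibility and verification

Identical configurations and seeds give byte-identical fixture files
and byte-identical reports. The test suite checks every stage against
independent oracles (union-find clustering, exhaustive chain
enumeration) and against the planted truth; `scripts/acceptance.R`
re-runs those checks against the installed package from a single
`--seed` and emits one flat JSON of the resulting quantities.

# Limitations

- Identification quality is bounded by the upstream searches; the
  package consumes their tabular output and cannot rescue genes the
  searches missed.
- The lineage count is a lower bound under loss, and depends on the
  assumed species tree and on support collapse; with very low support
  thresholds, collapsed polytomies can merge adjacent duplications.
- Duplication typing uses rank distances, so it is sensitive to the
  completeness of the background gene annotation (missing gene models
  shrink rank gaps).
- The expression stage is deliberately minimal: a threshold on mean
  abundance, no differential analysis.
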