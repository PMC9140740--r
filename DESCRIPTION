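Package: nbsurvey
Title: Genome-Wide Survey of NBS-LRR Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of the NBS-LRR
    (NLR) disease-resistance gene family. Identifies candidate family
    members from permissive homology-hit tables with a strict NB-ARC
    re-scan, classifies domain architectures into the TNL, CNL and RNL
    subclasses, calls gene clusters with a 250-kb chaining window,
    classifies duplication types (tandem, proximal, dispersed,
    segmental/WGD) over collinearity blocks detected by anchor chaining,
    and counts ancestral lineages on a rooted species-tagged gene tree by
    species-overlap reconciliation. Ships a synthetic-genome simulator
    that plants known architectures, clusters, duplication histories and
    birth-death gene trees so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
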