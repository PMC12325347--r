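Package: ProkTax
Title: Genome-Based Genus Delineation and Polysaccharide-Utilization
    Profiling for Prokaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-based prokaryotic taxonomy and functional
    profiling: average amino acid identity (AAI) over reciprocal best
    hits, percentage of conserved proteins (POCP), threshold-based genus
    delineation with merge proposals, detection of polysaccharide
    utilization loci (PULs) and CAZyme-rich gene clusters from annotated
    gene tables, 16S rRNA distance matrices and neighbor-joining trees
    with bootstrap supports, and KEGG-style metabolic module completeness.
    Includes a synthetic-data generator producing proteome pairs with
    controlled ortholog identity, gene tables with planted clusters, and
    alignments evolved on known trees, so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
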