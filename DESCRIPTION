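Package: panmarker
Title: Pan-Genome Marker Discovery and qPCR Assay Design for Bacterial
    Species and Subspecies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building species- and subspecies-specific
    real-time PCR assays from collections of labeled bacterial genomes.
    Clusters annotated genes into a pan-genome by greedy centroid
    clustering on global-alignment identity, partitions it into core,
    accessory and unique gene sets, builds pan-genome frequency and
    core-identity neighbor-joining trees to audit taxon labels, selects
    taxon-specific genetic markers by comparing taxon core genomes
    against all non-target genes, screens markers against plasmid
    replicons and mobile-element sequence sets, designs real-time PCR
    primer pairs on the markers under nearest-neighbor melting
    temperature constraints, verifies their specificity by in-silico
    PCR, and interprets qPCR readouts (standard curves, amplification
    efficiency, quantification, and product label-claim comparison).
    Includes a deterministic synthetic pan-genome simulator with planted
    taxon-specific markers so the full workflow is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
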