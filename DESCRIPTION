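Package: exonsite
Title: Projection of Protein Functional Sites onto Exon-Intron Gene Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how protein ligand-binding (functional) sites
    map onto the exon-intron structure of their coding genes. Provides exact
    residue-to-codon-to-exon coordinate mapping, exon 5'/3' phase and symmetry
    computation, classification of exons into site-coding (EC) and
    non-site-coding (ENC) samples, measurement of functional-site discontinuity
    (exon borders falling inside the site area) against a randomized
    exon-boundary null, and intron-phase analyses against a site-position
    permutation null. Includes a synthetic gene-structure and site-annotation
    generator with configurable exon-count, exon-length and junction-phase
    distributions, readers and writers for GTF and BED12 gene structures and
    TSV site tables, and an end-to-end pipeline producing reproducible,
    seed-stable report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
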