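Package: circplasmid
Title: Comparative Genomics of Small Circular Plasmid Families
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of families of small
    (~6 kb) circular plasmids such as the PL6 family of the haloarchaeon
    Haloquadratum walsbyi. Provides circular-coordinate sequence
    handling, circular ORF calling and operon detection, synteny-based
    gene-family assignment, protein statistics (length, identity,
    isoelectric point), rotation-aware pairwise and multiple alignment
    with neighbor-joining trees and bootstrap support, GC-profile
    segmentation into compositional domains, degenerate promoter/RBS
    motif scanning, inverted-repeat and conserved-intergenic-sequence
    detection, -1 programmed ribosomal frameshift signature analysis
    (slippery heptamer, stem-loop free energy, single-base insertion
    rescue), CRISPR spacer-protospacer matching with translated
    alignments, iterative read recruitment with de Bruijn assembly to
    circular closure, and a synthetic plasmid-family generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: mafft (for multiple alignment of three or more
    replicons)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
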