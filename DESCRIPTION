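Package: fadkit
Title: Characterization of Membrane-Bound Fatty Acid Desaturase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the computational characterization of
    membrane-bound fatty acid desaturase (FAD) gene families in plant genomes:
    candidate identification by local alignment against reference anchors with
    histidine-box architecture confirmation, conserved-motif analysis
    (histidine boxes, C-terminal ER-retrieval pentapeptide, N-terminal
    cytochrome b5 proxy), neighbor-joining phylogeny with Poisson-corrected
    distances and bootstrap support, tandem versus segmental duplication
    classification from GFF3 gene models, exon-intron structure comparison,
    and relative expression profiling by the 2^-ddCt method with hierarchical
    clustering of expression profiles. A synthetic-data generator produces
    genomes, proteomes and Ct tables with planted, recoverable features so the
    whole pipeline is testable without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
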