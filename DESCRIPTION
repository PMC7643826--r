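Package: sedcapture
Title: Metagenome Capture of Preserved Lake Microbiome DNA in Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects historical (preserved) water-column DNA in lake sediment
    shotgun metagenomes by directional fragment recruitment of unassembled
    sediment reads against overlying-source assemblies. Implements a
    seed-and-extend banded read aligner with explicit, recomputable percent
    identity arithmetic, empirical delineation of the identity threshold
    separating closely and distantly related populations, removal of scaffolds
    carrying conserved ribosomal and transfer RNA genes, capture accounting
    normalized by unassembled read counts, coverage-weighted taxonomic
    profiling, chord-transformed principal component analysis, Bray-Curtis
    dissimilarities with Ward dendrograms, masked reference-genome recruitment
    profiles, and a fully ground-truthed synthetic lake-system simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vegan,
    ape,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
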