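Package: motifboot
Title: Bootstrap Phylogenetic Footprinting for Bacterial Promoter Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcription factor binding sites in a
    bacterial target promoter by phylogenetic footprinting over many
    bootstrap subsets of orthologous promoters. Orthologous promoters are
    stratified by evolutionary distance to the target, resampled into
    fixed-quota subsets, and each subset is searched with de novo motif
    finders (a Gibbs site sampler and a word-enumeration finder) whose
    results are combined by voting. Motif positions on the target are
    accumulated into a run-support histogram with peak calling, discovered
    motifs are matched against a known-motif database with empirical
    p-values and E-values, and per-peak consolidated alignments and
    taxonomic presence maps are produced. A synthetic orthologous-promoter
    simulator with implanted conserved motifs makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
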