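Package: famevol
Title: Molecular Evolution Analysis of Plant Gene Families
Version: 1.0.0
Authors@R:
    person("Famevol", "Developers", email = "famevol@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide molecular-evolution analysis of plant gene
    families, modelled on the workflow used for the phospholipase D (PLD)
    family: membership calling from the duplicated HxKxxxxD catalytic motif,
    subfamily classification from N-terminal lipid-binding domains,
    neighbor-joining phylogenies with p-distance, complete deletion and
    bootstrap support, detection of same-species paralog pairs, classification
    of duplications as tandem or segmental from flanking-gene conservation,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction and
    sliding-window selection scans, molecular-clock dating of duplication
    events (T = Ks/2*lambda), protein motif-architecture comparison, and a
    seeded synthetic-genome generator with planted ground truth for testing
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
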