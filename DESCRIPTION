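Package: pondvirome
Title: Virome Profiling: Coverage-Normalized Abundance, Bit-Score Taxonomy,
    and Pol I Lifestyle Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for freshwater virome shotgun surveys and the
    accompanying 16S community tables. Computes per-contig and per-ORF
    coverage from read recruitment and normalizes it per gigabase pair of
    recruited reads; assigns contig taxonomy and ORF functional subsystems
    by the maximum summed bit score over homology hits; classifies family A
    DNA polymerase (Pol I) peptides as virulent or temperate phage from the
    residue at reference position 762 after semi-global alignment to a
    reference polymerase; and provides core-OTU set algebra, rarefaction and
    diversity computations for OTU tables. Ships seeded synthetic-data
    generators (viral community, Pol I peptide sets, OTU tables) with
    planted ground truth so every pipeline stage has parameter-recovery
    tests that run offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    Rcpp,
    Rsamtools,
    stats,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
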