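Package: mesamarker
Title: Group-Diagnostic SNP Markers and Comparative Analysis of Methyl
    Salicylate Biosynthesis Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative candidate-gene analysis of methyl
    salicylate (MeSA) biosynthesis genes (SAMT, SABP2) across birch
    species: IUPAC-aware polymorphism scanning of Sanger consensus
    sequences, discovery and validation of group-diagnostic SNP markers,
    heterozygosity profiling, conserved-residue verification in protein
    alignments, distance-based phylogeny (p-distance, neighbor joining,
    bootstrap) with group-monophyly testing, promoter cis-element
    consensus scanning with between-group frequency comparison, and
    delta-Ct relative expression analysis of RT-qPCR data. Includes
    synthetic-data generators with known ground truth for every pipeline
    stage and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
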