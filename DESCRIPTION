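Package: intronmine
Title: Mining Intron Markers for Multilocus Phylogenetics of Closely
    Related Species
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A genome-wide pipeline for mining exon-primed intron-crossing
    (EPIC) markers suitable for multilocus phylogenetics of closely related
    species.  Extracts introns and flanking exons from annotated genomes,
    builds one-to-one orthologous intron sets from pairwise gene-orthology
    tables, and applies a filter cascade: reference-species length bounds,
    cross-species length conservation, minimum flanking-exon size, a
    single-copy (anti-paralog) test on homology-search hit tables, a
    clock-likeness test based on the branch-length residual score of each
    intron tree against a concatenation reference tree, and a divergence
    test based on the least-squares tree scaling factor and the total
    branch length of the three-reference-taxon tree.  Surviving markers
    are annotated with SNP density, microsatellites, repeat content,
    species-pair divergences and degenerate-primer suggestions.  A fully
    labelled synthetic clade simulator with planted intron classes makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    phangorn,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
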