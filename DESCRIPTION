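Package: dupmosaic
Title: Duplicon Discovery and Mosaic Structure Analysis for Segmental
    Duplications and Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers duplicons, the minimal duplicated subunits (>= 100 bp)
    that compose the mosaic structure of segmental duplications (SDs) and
    copy number variants (CNVs). Alignment hits of SDs against CNV sequences
    are summarised as binary alignment matrices, duplicon segments are
    decoded with a three-state non-homogeneous hidden Markov model whose
    transition probabilities are driven by adjacent-column 0/1 patterns and
    whose emissions follow a cumulative binomial law, and each candidate is
    validated with a copy-number permutation test that relocates alignment
    runs. Downstream tools analyse the resulting mosaic: binary phylogenetic
    profiles and neighbor-joining trees of duplication segments, core
    duplicon detection within clades, flanking duplicon pairs at CNV ends
    (candidate substrates of nonallelic homologous recombination), and
    weighted duplicon density in CNV versus non-CNV regions. Includes
    synthetic-data generators with planted ground truth and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
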