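Package: zeameth
Title: Windowed DMR Calling, Methylation-Expression Association and
    Domestication Selection Tests for Maize Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse plant whole-genome bisulfite data at the
    resolution used in maize population epigenetics: parsing of
    Bismark-style cytosine reports, two windowed differentially
    methylated region (DMR) callers (a population-haplotype mode with a
    per-region t-test and a mutant-versus-wild-type threshold mode),
    annotation of DMRs against gene bodies, promoters and transposable
    elements with a two-proportion enrichment test for differentially
    expressed genes, nucleotide diversity (pi) and Watterson's theta on
    population alignments, and an ms-style coalescent simulator with a
    piecewise-constant domestication bottleneck that yields a
    simulation-based selection test on retained diversity. Seeded
    synthetic-data generators with truth tables make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
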