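Package: clonevar
Title: Intragenomic and Intergenomic Variation in Cloned Amplicon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intragenomic (within-individual) and intergenomic
    (among-individual) sequence variation in cloned PCR amplicon libraries of
    taxonomic marker genes such as mitochondrial CO1 and ribosomal ITS2.
    Collapses clones into paralogous haplotypes with a Taq-error singleton
    filter, computes gap-aware p-distances (gaps as a fifth character state)
    partitioned into intragenomic and intergenomic summaries, runs exact and
    Monte-Carlo permutation tests for gene, genome-partition and sex contrasts,
    screens mitochondrial haplotypes for numts and heteroplasmy and ITS2
    haplotypes for pseudogene signals, and simulates ground-truthed cloned
    amplicon libraries (multicopy rDNA arrays under tunable concerted
    evolution, mitochondrial templates with numts and heteroplasmy,
    haplodiploid sexes, per-cycle polymerase error) so every stage can be
    validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
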