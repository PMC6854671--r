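Package: indelchip
Title: Design and Genotype Calling for Insertion/Deletion Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("indelchip", "developers", email = "indelchip@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genotyping large insertions/deletions (including
    presence/absence variants) with a SNP-style fluorescence array:
    breakpoint classification by microhomology, k-mer based detection of
    presence/absence regions, design and windowed selection of breakpoint
    and internal probes, two-channel cluster-based genotype calling
    (including an intensity-only caller for monomorphic internal probes),
    multi-probe consensus genotyping with binomial error simulation, and
    downstream diversity analysis (IBD kinship, principal coordinates).
    Includes a synthetic-data module that generates genomes with planted
    InDels and array signals for fully reproducible desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
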