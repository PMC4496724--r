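Package: ampledit
Title: Amplicon Deep-Sequencing Analysis of Embryo Genome-Editing Outcomes
Version: 0.1.0
Authors@R:
    person("Ampledit", "Maintainers", email = "maintainers@ampledit.example.org",
           role = c("aut", "cre"))
Description: Quantifies genome-editing outcomes (wild-type alleles,
    oligonucleotide-templated precise edits, and random indels) in single
    embryos from paired-end amplicon deep-sequencing reads. Implements
    quality trimming to the longest high-quality segment, exact-overlap
    read-pair joining, length filtering, semi-global affine-gap mapping to
    a reference amplicon, key-window allele enumeration with a reporting
    threshold, allele classification with mosaicism calls, in-silico
    restriction digest and degenerate-probe diagnostics, and group-level
    statistics (exact tests and a binomial logit-link model on per-embryo
    read counts). Ships a seeded synthetic read generator that emulates
    the assay so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
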