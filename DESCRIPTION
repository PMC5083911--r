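Package: tespectrum
Title: Mutation Spectra of Transposable-Element Copies from Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates nucleotide mutation spectra of transposable-element
    (TE) families from gapped multiple sequence alignments of element copies
    sampled across field populations. Ancestral states are called per
    alignment column by a majority-rule threshold (optionally anchored on a
    designated ancestral copy), substitutions and indels are detected,
    adjacent substituted sites are merged into multi-base events, recurrent
    events are deduplicated, and events are classified by substitution
    pattern (transition/transversion, the 12 ordered base changes and their
    strand-pooled pairs), codon position, protein effect (synonymous,
    missense, nonsense, no-stop) and indel frame effect. Per-group spectra
    are summarized as means with standard errors and compared with pooled
    t-tests and one-way ANOVA with Tukey HSD post hoc tests and compact
    letter displays. A seeded TE-family simulator with a planted-event
    ledger makes every stage testable without external data.
License: MIT + file LICENSE
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
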