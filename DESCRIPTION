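Package: hypermutR
Title: APOBEC3 G-to-A Hypermutation Profiling of Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing APOBEC3-style G-to-A
    hypermutation in endogenous retroviruses such as the endogenous mouse
    mammary tumor virus (Mtv) proviruses. Provides pairwise alignment of
    proviruses against a reference, substitution classification and
    hypermutation summary statistics (percent G>A of mismatches, G>A per
    kilobase, runs of consecutive G>A), sliding-window mutation gradients,
    minus-strand trinucleotide target-site context analysis with sequence
    logos and deaminase allele preference calls, coding-impact scanning for
    premature stops and start-codon losses, 5'-versus-3' long terminal
    repeat comparison, diagnostic-site haplotype enumeration, and a
    ground-truth simulator of minus-strand cytidine deamination with
    context-dependent rates, cascade target creation, and 3' LTR
    re-exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
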