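Package: popfid
Title: Positive-Selection DNA Polymerase Fidelity Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for gap-filling forward-mutation fidelity
    assays of DNA polymerases scored by positive selection in E. coli.
    Aligns sequenced mutant reporter-gene clones to the reference and calls
    substitutions, single-base indels and complex mutations; summarises
    mutation spectra as template:dNMP mispair classes with chi-squared
    comparisons between enzymes; estimates mutant frequencies from colony
    counts and polymerase error rates both from detectable-site catalogues
    (ER = MF/(D x P)) and by scaling against a comparator enzyme; and
    provides a seeded Monte-Carlo simulator of the whole assay so every
    stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
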