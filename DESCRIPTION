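Package: fockconj
Title: Quantum Representations of Concept-Conjunction Membership Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing human membership judgements of concept
    conjunctions ("is a skateboard a Machine-And-Vehicle?") with quantum
    cognitive models. Classifies membership-weight triplets as classical or
    overextended, constructs complex Hilbert-space representations in the
    first (emergent, C^3) and second (logical, tensor-product) sectors of a
    two-sector Fock space, unifies whole datasets under a single conceptual
    state via unitary changes of basis, fits the two-sector Fock membership
    formula, and tests measurement compatibility of exemplar pairs through
    commutator expectation values. Includes a deterministic synthetic-data
    generator for every data regime and a small pipeline for CSV-to-JSON
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
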