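Package: albustab
Title: Covalent Albumin Binding and Plasma Stability of Thiol Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for peptide drugs whose free cysteine forms
    disulfide conjugates with plasma thiols and serum albumin: in-silico
    tryptic digestion, monoisotopic mass and elemental-composition
    arithmetic for disulfide-linked conjugates and low-molecular-weight
    thiol adducts, ppm-tolerance matching of observed masses with a
    reduction/alkylation consistency control, isotope-pattern prediction
    and extracted-ion-chromatogram quantification over incubation time
    courses, one-phase-decay half-life and 4PL IC50 dose-response fitting,
    and a seeded synthetic-data generator emulating plasma LC-MS and
    antibody-competition experiments with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    Biostrings,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
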