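Package: hgldtg
Title: Dereplication, Chemotyping and Candidate-Gene Discovery for
    17-Hydroxygeranyllinalool Diterpene Glycosides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based annotation of 17-hydroxygeranyllinalool diterpene
    glycosides (HGL-DTGs) from accurate-mass peak lists: monoisotopic mass and
    adduct m/z arithmetic, enumeration of hexose/deoxyhexose/malonyl
    decorations of the 17-HGL scaffold, MS/MS neutral-loss assignment, and
    chemotype classification into rhamnosylated, non-rhamnosylated and
    intermediate classes. Includes extracted-ion-chromatogram and peak-area
    chemotype profiling with internal-standard quantification and fold-change
    matrices, PSPG-motif scanning of UDP-glycosyltransferase proteomes with
    bait-gene co-expression candidate ranking, and seeded synthetic-data
    generators emulating the instrument and microarray designs the pipeline
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
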