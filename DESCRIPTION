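Package: cherryS
Title: S-Allele and MGST Genotyping for Sweet Cherry from Capillary Fragment
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls sweet cherry (Prunus avium) self-(in)compatibility genotypes
    from one-tube multiplex PCR fragment-analysis peak tables. Ships the assay
    panel (primers, dye-channel fragment bins, an internal PaveIF-1A control
    and peak-height dosage calibrations), bins capillary electrophoresis peaks
    to fragments, applies allele confirmation rules for 14 self-incompatible
    and 3 self-compatible S-alleles plus 3 MGST promoter alleles, and resolves
    single-S-allele ambiguities (S3S3', S3'S3', S4'S4', S5'S5') by copy-number
    dosage of control-normalized peak heights. Includes an in-silico multiplex
    PCR engine over IUPAC-degenerate primers and a seeded synthetic peak-table
    simulator with a copy-number height model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
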