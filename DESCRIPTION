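Package: phytorisk
Title: Soil-to-Crop Heavy-Metal Transfer and Dietary Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for food-safety studies of heavy metals (Hg, Pb, As) in
    soils and crops: Risk Assessment Code from sequential-extraction
    fractions, bioconcentration and translocation factors, Lichtenthaler
    chlorophyll and carotenoid quantification, analytical quality control
    (detection limits from method blanks, certified-reference-material
    recovery, left-censoring rules), and the dietary risk indices EDI, CDI,
    THQ, HI, ILCR, MOE and PTWI comparison, with a synthetic-study generator
    for end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
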