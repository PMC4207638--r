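Package: equicnv
Title: Copy Number Variant Discovery from Tiling Array CGH in the Horse
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Whole-genome array-CGH copy number analysis for the horse
    (EquCab2): simulation of 400K tiling-array hybridizations with planted
    copy number variants, derivative-log-ratio quality control, CNV calling
    by a thresholded-run rule, consolidation of per-sample calls into copy
    number variable regions (CNVRs), genic and sub-telomeric annotation,
    chromosome enrichment statistics, and positional integration of CNVR
    sets from multiple studies into a composite dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
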