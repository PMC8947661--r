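Package: liquidqc
Title: Analytic Validation Toolkit for Liquid-Biopsy NGS Variant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control gating, Levey-Jennings control charting, and
    analytic-validation statistics (limit of detection, specificity,
    repeatability and intermediate precision) for cell-free nucleic acid
    next-generation sequencing panels that report gene fusions, exon-skipping
    transcripts and copy-number amplifications. Includes a synthetic
    assay-output generator that emulates UMI molecular-family counts along a
    dilution series, fold-change attenuation of copy-number signal, internal
    process controls, negative donor cohorts and multi-run precision study
    designs, so that every pipeline stage can be exercised and tested without
    access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
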