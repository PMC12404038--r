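Package: panresistome
Title: Comparative Resistome Analysis from Subsystem Annotation Exports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds binary gene presence-absence matrices from per-strain
    functional annotation exports (subsystem-style Category / Subcategory /
    Subsystem / Role tables in TSV, CSV, XLS or XLSX), extracts stress- and
    resistance-related functions by keyword search, and computes the shared
    and exclusive resistome of a query strain against a panel of
    radiation-resistant and radiation-sensitive strains classified by their
    D10 dose. Ships a synthetic annotation-panel generator with planted
    resistome signatures for end-to-end validation, and deterministic
    clustered-heatmap reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    readxl,
    jsonlite,
    digest,
    yaml,
    viridisLite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
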