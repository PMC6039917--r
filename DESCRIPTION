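Package: copycatr
Title: Attribute-Keyed Network Layout Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns the layouts of two attributed networks by transferring
    node coordinates from a source network view to a target network view,
    matching nodes on a shared string- or integer-typed attribute column.
    Unmapped nodes on either side can be selected for downstream queries and
    unmapped target nodes can be placed on a grid beside the mapped layout;
    the source viewport (zoom and center) is cloned onto the target. Networks
    are read and written as Cytoscape.js JSON (.cyjs), GraphML, or SIF edge
    lists with side-car coordinate tables. A small HTTP service reproduces
    the Cytoscape Automation (CyREST) endpoint contract for the layout,
    including the CIResponse envelope and its 404 error semantics, so
    existing automation scripts work against it unchanged. Ships a seeded
    synthetic network-pair generator and a brute-force matching oracle used
    by the test suite.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    httpuv,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
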