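Package: pathora
Title: Pathway Diagram Construction, Data Overlay Visualisation and
    Z-Score Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Programmatic construction and editing of biological pathway
    diagrams in a GPML-dialect XML format, cross-mapping of gene and
    metabolite identifiers between database systems, linking of tabular
    omics measurements to pathway nodes, colour-gradient and colour-rule
    visualisation of multi-column data on nodes (SVG and PNG with image-map
    hit regions), Z-score over-representation analysis across a pathway
    collection with hypergeometric variance, and export of ranked,
    hyperlinked HTML reports with per-element back pages.  All operations
    are scriptable through the library API, a batch command-line interface,
    and a namespaced XML-RPC server.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    png,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
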