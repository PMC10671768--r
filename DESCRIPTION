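Package: hubdiag
Title: Hub-Based Theranostic Diagnosis from Interactomes and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for prioritizing therapeutic targets in cancer from a
    protein-protein interaction network and paired tumor/control RNA-seq
    profiles. Reads PSI-MITAB or plain edge lists, normalizes counts to RPKM,
    calls up-regulated genes by a population-level z-test on signed-log
    expression differences, ranks connectivity hubs in the up-regulated
    subnetwork, quantifies network Shannon entropy (vertex and degree-class
    variants) and its drop under targeted hub removal, calibrates a linear
    entropy to 5-year overall-survival relationship by orthogonal (total
    least squares) regression, and estimates how many hubs must be inhibited
    to reach a survival goal. Includes a seeded generator of scale-free
    interactomes with planted up-regulated hubs for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
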