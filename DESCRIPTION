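Package: pdod
Title: Predicting Drugs with Opposite Effects on Disease Genes in Signed
    Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based drug repositioning that scores how likely a drug
    is to reverse the up- or down-regulated states of a disease's genes.
    Drug targets are propagated through a signed directed molecular network
    (activation/expression edges +1, inhibition/repression edges -1) using
    conflict-adjusted shortest-path distances: all shortest paths between a
    drug target and a disease gene are classified as activation-like or
    inhibition-like by the parity of their inhibition edges, and ties
    between the two classes yield an infinite (uninformative) distance.
    Distances feed a bell-shaped kernel and a sign term combining drug
    action type, net path sign and gene state into the PDOD score, together
    with a directionless baseline (PDD) and AUC-based ranking evaluation.
    Includes parsers for edge tables, drug-target interaction tables,
    disease gene sets and KGML pathway files, a synthetic-data generator
    with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
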