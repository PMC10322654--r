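Package: ruleminer
Title: Automatic Extraction, Generalization and Evaluation of
    Biotransformation Reaction Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines transformation rules from atom-mapped biotransformation
    reactions. Reactions are clustered by exact reaction-center fingerprint
    identity, one composite SMIRKS rule is generalized per cluster by
    diameter expansion and co-occurrence-aware graph combination, and rule
    genericity (the negative-to-positive sample ratio) is tuned against a
    compound universe. A persisted rule set can be updated incrementally
    with new reactions. The package also implements the downstream pathway
    prediction evaluation stack: multi-label classifier chains over
    structural keys and rule-trigger bits, reaction-level (single
    generation) and pathway-level (multi generation) precision/recall with
    probability-threshold sweeps, and a genericity-scan protocol for
    selecting the optimal rule genericity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
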