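Package: mfhrag
Title: Retrieval-Augmented Dietary Recommendation over an Uncertain
    Medicine-Food-Homology Knowledge Graph
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, completes and queries an uncertain knowledge graph of
    medicine-food-homology (MFH) knowledge, where every fact is a quadruple
    (head, relation, tail, confidence).  Reasoning paths retrieved for a
    user query are ranked by a confidence-weighted PageRank combined with
    path reliability, the graph is completed by adding candidate triples
    whose predicted confidence exceeds a threshold, and an automated
    Hits@1/F1 harness evaluates retrieval quality.  A pluggable LLM gateway
    with a deterministic mock client and transcript record/replay, plus a
    synthetic knowledge-graph generator with planted gold paths, make the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
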