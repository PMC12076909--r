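Package: retrodiv
Title: Diversity-Oriented Retrosynthetic Route Search on AND/OR Reaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Proof-number search methods for retrosynthetic planning on
    AND/OR reaction networks: proof-number search (PNS), depth-first
    proof-number search (DFPN) with the threshold controlling algorithm
    (TCA) and graph-history-aware proof caching, and a multi-solution
    variant (DFPN*) that iterates the search with path-keyed forced
    disproofs and proof-number penalties to produce diverse sets of
    synthesis routes. Includes a Monte-Carlo tree search baseline, the
    chemical diversity score (CDS) for route sets based on Jaccard
    distances between bond-disconnection sets, seeded generators for
    synthetic reaction networks with planted routes, and a small
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
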