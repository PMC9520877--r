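Package: tucan
Title: Tuple-Based Canonical Molecular Identifiers for the Whole Periodic Table
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Canonicalizes molecular graphs read from molfile v3000 input and
    serializes them into the TUCAN tuple-style line notation
    (Hill formula / sorted edge tuples / node features). The identifier is
    element-agnostic from hydrogen to oganesson: canonical labels are derived
    from atomic numbers and graph topology alone, via invariant codes,
    iterative Weisfeiler-Lehman partition refinement, and an
    individualization-refinement stage with minimal-serialization
    tie-breaking. Strings are bidirectional: a deserializer reconstructs the
    molecular graph and a coordinate-free molfile. Includes a fixture library
    spanning organic, organometallic, main-group and symmetric non-chemical
    graphs, and a shuffle-test harness for validating permutation invariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, optparse, jsonlite
Config/testthat/edition: 3
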