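Package: mpdiagram
Title: Molecular Process Diagrams for Rule-Based Models
Version: 0.1.0
Authors@R: person("Maintainer", "mpdiagram", email = "mpdiagram@example.org",
    role = c("aut", "cre"))
Description: Parses rule-based biochemical models written in a BioNetGen
    language (BNGL) dialect, classifies each reaction rule's molecular
    sites as modified, context, or unconstrained, and builds Molecular
    Process Diagrams: bipartite graphs of molecular-complex nodes and
    process nodes at three resolution levels. Diagrams are exported as
    GraphML, SBGN-ML 0.2 Process Description maps with strippable
    annotation extensions, and DOT. Includes brute-force pattern matching
    and single-rule expansion into concrete reactions as a validation
    oracle, plus a seeded random-model generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
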