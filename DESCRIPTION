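Package: radsize
Title: Ontology-Based Classification of Radiology Size Measurements and
    RECIST Response Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents size measurements reported in radiology exams over
    an anatomical concept hierarchy, classifies them as normal, abnormal or
    unclassified by retrieving the most specific applicable normal-size
    specification via Entity-Quality matching, and evaluates tumor response
    over time with the RECIST 1.1 rules (target-lesion candidacy, selection
    verification, diameter sums, CR/PR/PD/SD labels). Findings,
    specifications and RECIST results can be exported as an RDF knowledge
    graph (Turtle) with an equivalent query-based classification path, and
    reviewed longitudinally in a red/green text or HTML viewer. A packaged
    mini knowledge base and a seeded synthetic cohort generator make every
    component testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
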