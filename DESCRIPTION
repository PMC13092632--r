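Package: clinlink
Title: Zero-Shot Clinical Abbreviation Disambiguation, SNOMED-CT Entity
    Linking and Heart-Failure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit that turns free-text clinical notes into
    standardized terminology concepts and diagnosis predictions. It detects
    and disambiguates medical abbreviations from dictionary pattern matching
    plus context-embedding similarity, links free-text spans to SNOMED-CT or
    UMLS concepts through a two-phase semantic candidate identification and
    selection algorithm (threshold filtering, concept pinpointing,
    positive/negative context collections with online learning, and nesting
    minimization), builds TF-IDF weighted concept-plus-ancestor patient
    vectors fused with normalized EHR features, and cross-validates a
    hinge-loss linear support vector machine over the four heart-failure
    diagnosis classes. Ships readers for SNOMED-CT RF2 snapshots, UMLS RRF
    tables, MedMentions PubTator and ShARe/CLEF-style standoff annotations,
    a deterministic feature-hashing embedding provider for fully offline
    operation, the complete evaluation metric suite (precision, recall, F1,
    expansion and total accuracy, Cohen's kappa, absolute agreement,
    confusion matrices), and seeded synthetic-fixture generators that
    emulate every licensed corpus the method is normally run on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
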