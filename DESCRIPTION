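Package: annohub
Title: An Offline Data Hub and Query Service for Biomedical Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A plugin-driven data hub for integrating biomedical annotation
    documents from disparate sources. Data-source plugins (a manifest plus a
    parser) are registered, their payloads dumped into versioned release
    folders with content-checksum release detection, parsed into validated
    JSON documents, merged across sources by shared entity identifier with
    source-namespaced bodies and root-source gating, profiled by a type
    inspector that derives a typed index mapping, indexed into an embedded
    inverted index, and served over HTTP with annotation-by-id, query, batch
    and metadata endpoints. Includes a deterministic synthetic-fixture
    generator and brute-force query oracle so every stage is testable
    offline, and an operator command-line console.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    curl,
    callr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
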