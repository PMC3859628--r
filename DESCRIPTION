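Package: adrsub
Title: Signal Substantiation for Pharmacovigilance Drug-Event Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A plugin-style engine for substantiating adverse-drug-reaction
    signals. Independent knowledge providers score drug-event pairs in [0,1]
    against local knowledge sources: a literature provider counting
    MeSH-annotated publications under the "adverse effects" / "chemically
    induced" subheading rule, a co-occurrence provider applying a chi-square
    test to 2x2 document-count tables per resource, and a target provider
    intersecting drug-target and event-target protein profiles with pathway
    annotation. A Dempster-Shafer combiner fuses the per-provider scores
    under configurable weights into belief, plausibility and a
    Low/Moderate/High risk tier. Providers communicate through a canonical,
    validated XML interchange dialect, and a seeded synthetic-world generator
    produces all knowledge sources with planted true associations for
    offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
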