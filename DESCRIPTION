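Package: litsignal
Title: Rule-Based Extraction of Signaling Events and Interaction Networks
    from Biomedical Text
Version: 0.1.0
Authors@R:
    person("litsignal", "developers", email = "litsignal@example.org",
           role = c("aut", "cre"))
Description: A cascade of interpretable, rule-based extractors that reads
    biomedical text and produces grounded molecular interactions. The
    pipeline segments and tokenizes text (or ingests gold CoNLL-U parses),
    recognizes and grounds entity mentions against knowledge-base
    dictionaries, matches parameterized dependency- and surface-pattern
    rule templates to extract simple biochemical events (post-translational
    modifications, binding, hydrolysis, translocation) and nested
    regulations and activations, corrects event polarity along syntactic
    dependency paths, resolves entity and event coreference with a
    precision-ordered sieve cascade, and assembles evidence-counted
    interaction records that can be filtered for redundancy and merged
    with curated prior networks in SIF format. Ships a deterministic
    synthetic gold-corpus generator and a recursive event scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
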