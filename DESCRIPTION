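Package: signcon
Title: Sign-Consistency Analysis of Gene Regulatory Networks Against
    Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how consistent a signed transcriptional regulatory
    network (activating/repressing TF-to-gene and TF-to-transcription-unit
    interactions, e.g. a RegulonDB export) is with a log-scale gene
    expression compendium. Implements a ternary sign-consistency model over
    per-experiment contrasts, per-edge and per-target inconsistency vectors,
    the global inconsistency load, two degree-preserving null models
    (expression-profile shuffling and edge rewiring), correlation analyses
    of TF-target expression profiles stratified by regulation sign, and a
    synthetic generator of signed networks and compendia under causal,
    decoupled and confounded regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
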