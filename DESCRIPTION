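Package: condortho
Title: Conditional Orthology Assignment and Cross-Species Expression
    Comparison for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns de novo assembled transcripts to reference genes by
    self-training a length-conditioned e-value threshold curve on
    reciprocal best-BLAST hits, then classifying remaining hits against
    the curve. Aggregates transcript-level abundance estimates to
    reference-gene level, normalises libraries with median-of-ratios size
    factors, classifies genes over an ordered developmental gradient into
    behaviourally discrete ascending and descending profile groups (26
    groups for a four-stage gradient), links two species' gene sets
    through an intermediary reference genome, and tests transcription
    factor co-occupancy of behaviour groups with a seeded Monte Carlo
    resampling procedure. Ships generators that produce every input with
    planted ground truth, so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
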