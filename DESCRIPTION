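Package: tcensemble
Title: Consensus Time-Course Differential Expression and Pathway
    Crosstalk Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects early transcriptional responses in short inhibitor
    time-course RNA-seq experiments by combining four independent
    per-gene detectors (per-timepoint negative-binomial Wald tests, an
    impulse-model negative-binomial likelihood-ratio test, a natural
    cubic spline moderated F-test, and a two-stage polynomial screen)
    through consensus voting with positive-control-anchored fold-change
    thresholds. Candidate genes are assembled into score-weighted
    protein-interaction subnetworks with temporal first-response
    annotation; networks from two inhibition experiments can be merged
    and their crosstalk subnetwork extracted with direction-concordance
    classification. Includes a negative-binomial count simulator with
    known ground truth emulating a 3/6/9-hour treated versus
    solvent-control design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
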