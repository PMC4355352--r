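Package: follistage
Title: Staging and Transcriptomic Analysis of Bovine Dominant Follicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stages bovine dominant ovarian follicles as growing, plateau or
    atretic from flow-cytometry DNA-content profiles of granulosa cells, and
    runs the downstream validation pipeline: gating and DNA-content histogram
    deconvolution with sub-G1 apoptosis quantification, proportion
    normalization and x-score ranking, loop-design two-color microarray
    differential expression with empirical-Bayes moderated statistics,
    between-group ordination, gene-set and signed-regulon enrichment, and
    qPCR quantification with geNORM reference-gene normalization and the
    stage-comparison test battery. Includes synthetic-data generators with
    known ground truth for every input so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    limma,
    pracma,
    cluster,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
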