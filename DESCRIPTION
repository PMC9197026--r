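Package: shmindel
Title: Probabilistic Inference of Somatic Hypermutation Indel Statistics in Antibody Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to learn the statistics of somatic-hypermutation-induced
    insertions and deletions in antibody V segments from repertoire
    sequencing data. Implements a generative model of point mutations and
    indels with a per-sequence hidden maturation age, a forward algorithm
    that sums the likelihood over all alignment scenarios between a read and
    its germline template, maximum-likelihood inference of the model
    parameters by expectation-maximization combined with projected momentum
    gradient ascent, a deterministic affine-gap Needleman-Wunsch annotation
    baseline with log-odds penalties, a synthetic-repertoire generator with
    ground-truth mutation scenarios, and descriptive indel summary statistics
    (event counts, length profiles, positional profiles, flank overlaps,
    inter-deletion distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
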