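Package: deltaES
Title: Recency-Weighted Evidence Integration in Sequential Information Gathering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequential information-gathering (beads-style)
    tasks in which participants sample evidence draw by draw before committing
    to a binary choice. Implements evidence-strength feature construction
    (cumulative evidence ES, its update dES, and chosen-relative evidence),
    penalized logistic stopping models fit per subject with a two-stage
    (meta-analytic) group level, a recency-bias metric, participant filtering
    and Tukey-fence outlier exclusion, bootstrap mediation of confidence
    through evidence sensitivity, iterative random-subset lasso decoding of
    decision variables from multichannel epoch data with searchlight mapping
    and peak-latency extraction, and cluster-based permutation inference on
    decodability timecourses. Ships a synthetic-data generator (task
    sequences, stopping agents, subject populations, sensor layouts, epochs
    with embedded spatiotemporal patterns) so every stage can be validated
    end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    metafor,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
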