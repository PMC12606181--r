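Package: dyadseq
Title: Dyadic Behavioural Escalation Sequences in Newly Introduced Social Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether unfamiliar animals escalate
    affiliative behaviour from low-risk to high-risk ("testing the waters")
    when relationships form. Bins time-stamped dyadic observation streams into
    5-minute presence/absence records, classifies each dyad's first-occurrence
    sequence against generalized and precise low-moderate-high predictions,
    builds a time-bin-shuffling permutation null that controls for behaviour
    frequencies, fits a Bayesian multi-membership Bernoulli model of the
    familiarity effect on sequence adherence, and compares pre-contact
    proximity rates with a sign-flip paired permutation test. Includes a
    synthetic observation-stream generator with known ground truth for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
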