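Package: pubbias
Title: Expected Power, Posterior Probability and Publication Bias from
    Observed Replication Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates meta-properties of a published scientific literature
    from its observed replication rate. Implements the closed-form Bayesian
    identities linking prior probability, statistical power, posterior
    probability and reproducibility under null-hypothesis significance
    testing; variance-aware expectations that integrate the posterior over
    Beta and bimodal Beta-mixture distributions of per-study power; a
    root-finding solver that recovers the expected power of original studies
    consistent with an observed replication rate for any assumed prior;
    publication-bias odds against a literature with a given share of positive
    findings; an exact binomial test of literature bias; and a seeded
    Monte-Carlo simulator of the study-publication-replication process used
    to validate the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
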