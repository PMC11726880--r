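Package: cashr
Title: Comparative Analysis of Shapley Values for Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects differentially expressed genes in case/control
    transcriptomic experiments by treating abnormal expression as a
    cooperative game. Expression values are discretized relative to the
    control group (mean plus/minus one standard deviation), microarray
    games are built per sample group, and each gene's Shapley value
    quantifies its contribution to the group's overall expression
    changes. Significance of the case-versus-control Shapley difference
    is assessed with a pooled-column bootstrap, followed by
    Benjamini-Hochberg correction and fold-change filtering. Classical
    baselines (Welch's unequal-variance t-test and an empirical-Bayes
    moderated t-statistic) and a synthetic-data generator with planted,
    partially penetrant effects are included for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
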