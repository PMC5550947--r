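Package: bbdisp
Title: Base-Level Beta-Binomial Modeling of RNA-Seq Read-Start Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models per-base read-start counts of two RNA-seq samples with a
    beta-binomial distribution whose overdispersion rate varies log-linearly
    with per-position sequencing depth and with the local sequence flanking
    the read start (random-hexamer priming bias). Provides method-of-moments
    estimation of the per-position overdispersion rate from replicate pairs,
    least-squares fitting of nested overdispersion models, a likelihood-ratio
    test for differential expression with pair-specific library factors,
    model comparison by nested chi-square tests and AIC, dispersion-versus-
    depth and positional diagnostics, and a simulator that generates
    base-level counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    Biostrings,
    Rsamtools
Config/testthat/edition: 3
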