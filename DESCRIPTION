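Package: dmscore
Title: Enrichment Scoring and Replicate Error Models for Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein variants from deep mutational scanning count data.
    Sequencing reads are quality filtered and variants are called alignment-free
    against a wild-type reference (directly sequenced or barcoded libraries).
    Per-selection enrichment scores are the slopes of wild-type-normalized log
    ratios regressed on normalized time, weighted by inverse Poisson variances;
    two-timepoint designs fall back to a ratio score with a closed-form standard
    error. Replicate scores are combined with a single-random-effect
    meta-analysis model fit by Fisher scoring, yielding per-variant scores and
    standard errors that support filtering, z-tests against wild-type, and
    between-condition comparisons. A selection simulator (binomial binding
    rounds, pure-birth growth) with known true effects, replicate-effect noise,
    and amplification/depletion jackpot noise is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
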