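Package: bsm5c
Title: Bisulfite-Sequencing Analysis of 5-Methylcytosine in RNA and DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale toolkit for calling 5-methylcytosine (m5C) sites from
    bisulfite-converted RNA sequencing data and for targeted clone-based
    bisulfite sequencing analysis. Provides a seeded simulator of
    bisulfite-converted reads with spike-in conversion controls, a simplified
    conversion-aware (three-letter) read mapper over a transcript reference,
    per-cytosine pileups and non-conversion levels, the 30RC/5C/80CT/10MM
    candidate-site filters with a strict single-replicate fallback,
    Fisher-exact differential methylation with Benjamini-Hochberg correction,
    bisulfite-aware clone alignment with an incomplete-conversion clone
    filter, and methylation-expression-clinical association statistics
    (Spearman, t-test, Fisher 2x2, exact and asymptotic chi-square,
    actinomycin-chase half-life estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
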