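Package: targetmr
Title: Drug-Target Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Drug-target Mendelian randomization from GWAS summary
    statistics: cis instrument construction with LD clumping and
    F-statistic filtering, allele harmonization, a five-estimator causal
    suite (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median, mode-based) with Cochran's Q and MR-Egger intercept
    diagnostics, positive-control gating, Benjamini-Hochberg false
    discovery rate control, and two-step mediation-proportion estimation,
    plus a summary-statistic simulator with known causal structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
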