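Package: amplibeta
Title: LINE-1 Bisulfite Amplicon Methylation Quantification and
    Immunotherapy Response Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies LINE-1 methylation from targeted bisulfite amplicon
    sequencing reads: assigns reads to probe templates, filters indel reads,
    counts strand-separated methylated and converted bases, estimates the
    per-sample bisulfite conversion rate from naive cytosines and computes
    conversion-corrected beta values. Evaluates genomic hypomethylation as a
    biomarker of response to immune checkpoint blockade via randomized probe
    weighting, mean-split survival stratification with a signed log-rank P
    bootstrap, logistic-regression ROC-AUC response prediction, and paired
    longitudinal differential-methylation monitoring. Includes a synthetic
    read and cohort generator with a tumor-purity mixture model for in silico
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
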