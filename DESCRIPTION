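Package: mirloop
Title: Detection of Deregulated miRNA/TF-Mediated Regulatory Loops from
    Two-Condition Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrative detection of deregulated miRNA/transcription-factor
    regulatory loops from paired mRNA and miRNA expression matrices measured
    under two biological conditions (e.g. normal versus tumor tissue).
    Differential expression is assessed with surrogate-variable-adjusted
    empirical-Bayes moderated t-statistics under Benjamini-Hochberg false
    discovery rate control; regulators missed by per-transcript testing are
    rescued by Wilcoxon rank-sum gene-set enrichment over transcription-factor
    target, validated miRNA target, and pathway gene-set families. Regulatory
    priors (TF-gene, TF-miRNA, predicted and validated miRNA-gene tables) are
    then restricted to deregulated regulators and composed into Type I and
    Type II (A/B, coherent/incoherent) feed-forward loops and Type III pathway
    loops. Loops are scored with Fisher's combined probability statistic
    (chi-square, six degrees of freedom), labeled for consistency between node
    deregulation directions and edge signs, and labeled for miRNA-target
    evidence. A synthetic-data generator with planted ground truth supports
    end-to-end validation, and a pipeline driver orchestrates all stages from
    a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
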