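Package: mrtriage
Title: Proteome-Wide Mendelian Randomization Triage of Plasma-Protein Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) of plasma-protein exposures
    on disease outcomes from GWAS summary statistics, with the full evidence
    chain used to triage candidate drug targets: cis-pQTL instrument selection
    (cis window, genome-wide significance, LD clumping, MHC exclusion), allele
    harmonization, a suite of causal-effect estimators (Wald ratio, IVW,
    MR-Egger, weighted median, MR-PRESSO, robust adjusted profile score) with
    an estimator-preference policy and FDR control, Steiger directionality and
    reverse-MR exclusion, multi-cohort fixed/DerSimonian-Laird meta-analysis
    with an I-squared model switch, single-causal-variant Bayesian
    colocalization from Wakefield approximate Bayes factors, TWAS/PWAS
    weighted-score external validation, protein-protein interaction drug-target
    linkage, and a four-tier evidence grading of targets. Seeded generators of
    synthetic GWAS summary statistics with known ground truth support
    calibration and end-to-end testing without individual-level data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse,
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
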