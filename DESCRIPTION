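Package: HRDevidence
Title: Calibrating Tumour Homologous-Recombination Status as Germline
    BRCA1/BRCA2 Variant Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates breast-tumour homologous-recombination (HR) status
    as weighted ACMG/AMP evidence for germline BRCA1/BRCA2 variant
    classification. Provides germline variant curation into three classes
    and six categories with patient grouping into five germline groups;
    dichotomisation of CHORD, HRDetect and HRDsum predictions at their
    published thresholds with CHORD gene-subtype assignment; a simplified
    HRDsum genomic-scar score (HRD-LOH + LST + NtAI) computed from
    allele-specific copy-number segments; Haldane-corrected likelihood
    ratios with Katz log-scale confidence intervals and Bayesian conversion
    to ACMG/AMP evidence strengths and points; chi-square/Cramer's V and
    Wilcoxon rank-sum association statistics; and a synthetic cohort
    simulator for end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
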