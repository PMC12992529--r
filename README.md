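# HRDevidence

Calibrates breast-tumour homologous-recombination (HR) status as weighted
ACMG/AMP evidence for classifying germline *BRCA1*/*BRCA2* variants.

Tumours arising in carriers of pathogenic *BRCA1/2* germline variants are
usually HR-deficient (HRD), while tumours of non-carriers are usually
HR-proficient (HRP). Comparing the HR-category proportions between
germline-positive and germline-negative patients yields a likelihood
ratio (LR) for variant pathogenicity,

    LR = p_case / p_ctrl,   p = x / n per group,

with a Haldane 0.5 continuity correction on zero cells and a Katz
log-scale Wald 95% confidence interval,

    exp( ln LR ± 1.96 · sqrt( (1−p_case)/(n_case·p_case)
                            + (1−p_ctrl)/(n_ctrl·p_ctrl) ) ).

The LR is converted to an ACMG/AMP evidence strength through the Bayesian
points framework — thresholds 350^(1/8), 350^(1/4), 350^(1/2), 350 for
Supporting (+1), Moderate (+2), Strong (+4), Very Strong (+8), mirrored
at the reciprocals on the benign side — with zero points forced when the
confidence interval contains 1.

Around this core the package provides, as plain functions with TSV
readers/writers:

* **Variant curation** — collapse of ClinVar/gnomAD annotations to
  P/LP / VUS / B/LB, the six A–F variant categories, and the five-group
  patient partition (*BRCA1*-positive, *BRCA2*-positive, negative,
  Excluded, *BRCA1/2*-VUS).
* **HR prediction calls** — CHORD (> 0.5), HRDetect (> 0.7) and HRDsum
  (≥ 42) dichotomisation, CHORD *BRCA1*/*BRCA2*-subtype assignment, and
  cross-tool concordance tables.
* **Scar score** — a simplified HRDsum (HRD-LOH + LST + NtAI) computed
  from allele-specific copy-number segments.
* **Calibration** — `hr_calibration()` returns a classed fit with
  `print()`, `summary()`, `coef()` and `confint()` methods, plus a
  sensitivity reanalysis including Excluded carriers and a per-VUS
  evidence report.
* **Association statistics** — chi-square, Cramér's V and a rank-sum
  test (exact by enumeration at small n) for pathology-marker analyses.
* **Cohort simulator** — deterministic fixture and stochastic synthetic
  cohorts with the published group structure, so the whole pipeline is
  testable without patient data.

## Worked example

```r
library(HRDevidence)

cohort    <- fixture_cohort()                       # 350 synthetic patients
partition <- partition_cohort(curate_variants(cohort$variants),
                              cohort$samples)
partition$counts
#> BRCA1_POS  BRCA2_POS   NEGATIVE   EXCLUDED BRCA12_VUS
#>        27         21        232         62          8

calls <- call_hr(cohort$scores, "CHORD")
fit   <- hr_calibration(partition, calls, tool = "CHORD")
fit
#> HR-status evidence calibration (CHORD)
#>
#> BRCA1 - Dichotomous
#>  category   negative  positive       LR (95% CI)                 evidence
#>       HRP 197 (0.85)  0 (0.00) 0.02 (0.00, 0.33)       Benign Strong (-4)
#>       HRD  35 (0.15) 27 (1.00) 6.63 (4.88, 9.00) Pathogenic Moderate (+2)
#>
#> BRCA1 - Stratified by subtype
#>           category   negative  positive         LR (95% CI) ...
#>  HRD BRCA1 subtype  17 (0.07) 27 (1.00) 13.65 (8.64, 21.57) Pathogenic Moderate (+2)
#>  HRD BRCA2 subtype  15 (0.06)  0 (0.00)   0.27 (0.02, 4.37) Not significant (+0)
#> ...
```

Reading: an HRP tumour in a *BRCA1* variant carrier is strong evidence
against pathogenicity of that variant (−4 points); an HRD tumour is
moderate evidence for it (+2); an HRD tumour of the *opposite* CHORD
subtype carries no usable evidence (the interval spans 1). A scar-score
example:

```r
genome   <- toy_genome()
segments <- simulate_segments("HRD", genome, seed = 7)
score_scars(segments, genome)
#> HRDsum 115 (LOH 22 + LST 71 + NtAI 22) -> HRD (cut 42)
```

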