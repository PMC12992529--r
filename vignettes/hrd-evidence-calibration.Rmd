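---
title: "Calibrating tumour HR status as germline BRCA1/2 variant evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating tumour HR status as germline BRCA1/2 variant evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HRDevidence)
```

## The problem

Pathogenic germline variants in *BRCA1* and *BRCA2* disable homologous
recombination (HR), and the tumours that arise in carriers accumulate a
characteristic pattern of somatic damage ("genomic scars"). Tools such as
CHORD, HRDetect and the HRDsum scar score read this pattern off a tumour
genome and call it HR-deficient (HRD) or HR-proficient (HRP). If HRD
tumours are much more common in carriers of pathogenic *BRCA1/2* variants
than in non-carriers, then observing a patient's tumour HR status carries
information about the pathogenicity of whatever rare *BRCA1/2* germline
variant that patient carries — exactly the kind of information the
ACMG/AMP classification framework can absorb as a weighted evidence item.
This package implements that calibration: it turns tumour HR calls into
likelihood ratios (LRs) for germline variant pathogenicity and converts
them into ACMG/AMP evidence strengths and points, with every supporting
step (variant curation, HR dichotomisation, scar scoring, cohort
simulation, association statistics) included and testable.

## Cohort structure: categories and groups

Each germline variant in the 11-gene panel (*BRCA1*, *BRCA2*, *ATM*,
*BARD1*, *BRIP1*, *CHEK2*, *PALB2*, *PTEN*, *RAD51C*, *RAD51D*, *TP53*)
is collapsed to one of three classes — pathogenic/likely pathogenic
(P/LP), VUS, or benign/likely benign (B/LB) — and then to one of six
categories crossing class with gene set: A (P/LP in *BRCA1/2*), B (P/LP
in another panel gene, conservatively including "suspicious" VUS), C (VUS
in *BRCA1/2*), D (VUS in another gene), E and F (B/LB). The collapse
rule is deliberately blunt: a gnomAD filtering allele frequency at or
above `faf_max` (default 1e-4) forces B/LB — a variant that common cannot
be a high-penetrance breast-cancer allele — otherwise a ClinVar P/LP or
B/LB assertion stands, and everything else is VUS. Bioinformatic scores
(BayesDel, SpliceAI, CADD) never set the class on their own; at most they
mark a VUS as suspicious. A precomputed `class3` column bypasses the
collapse entirely, which is how externally curated calls (expert-panel
classifications, classified structural variants) enter.

Patients are then partitioned into five groups: *BRCA1*-positive,
*BRCA2*-positive, *BRCA1/2*-negative, Excluded (P/LP or only VUS in the
other panel genes — removed so that HRD driven by, say, *PALB2* does not
contaminate the negative reference set), and *BRCA1/2*-VUS (held out for
the per-variant evidence report). Exclusion is checked first; among
carriers, *BRCA1* outranks *BRCA2* (with a warning; the combination is
not expected in practice).

Two rules were genuinely open and are settled here as package defaults,
both configurable. First, a patient carrying a *BRCA1/2* P/LP variant
plus a plain VUS in another gene is assigned to the positive group (the
exclusion rule for other-gene VUS applies only when there is no *BRCA1/2*
P/LP or VUS); `strict_exclusion = TRUE` gives the other reading. Second,
"suspicious VUS" is an input flag rather than a hard-coded score rule,
because no published cutoff defines it; optional BayesDel/SpliceAI
cutoffs can derive it.

## HR dichotomisation and CHORD subtypes

The three tools' scores are consumed, never recomputed: CHORD calls HRD
at probability > 0.5, HRDetect at > 0.7 (both strict inequalities),
HRDsum at a scar sum ≥ 42 (inclusive; the FDA-recognised cutoff for PARP
inhibitor selection). CHORD additionally decomposes its HRD probability
into *BRCA1*-type and *BRCA2*-type components. An HRD tumour is assigned
the larger component's subtype when that maximum reaches
`subtype_min_prob` (default 0.5); below it, or on an exact tie, the
subtype is undetermined. This surrogate rule is a documented stand-in for
CHORD's own internal undetermined criteria (which depend on mutation
counts the package never sees); the threshold is configurable, and
undetermined HRD tumours stay in the group denominators while counting
towards no subtype.

## The scar score

HRDsum is the sum of three counts computed from allele-specific
copy-number segments (0-based half-open coordinates; a flag converts
1-based inclusive input):

* **HRD-LOH** — segments with minor allele count 0, at least 15 Mb long,
  not spanning the whole chromosome (whole-chromosome LOH reflects
  chromosome loss, not recombination failure).
* **LST** — after discarding segments shorter than 3 Mb and re-merging
  identical neighbours, copy-number-changing junctions whose flanking
  segments are both ≥ 10 Mb, whose gap is < 3 Mb, and which do not cross
  the centromere.
* **NtAI** — maximal runs of allelic imbalance (major ≠ minor) that touch
  a chromosome end, stay on one side of the centromere, do not span the
  whole chromosome, and are ≥ 11 Mb.

These operational definitions follow the widely used scar-score
conventions; the source scar literature defines the sub-scores with minor
variations, so every length parameter is exposed (`loh_min`,
`lst_smooth`, `lst_flank`, `ntai_min`, `cut`). Two simplifications are
deliberate and documented limitations: allelic imbalance is defined
relative to 1:1 rather than to tumour ploidy, and no purity/ploidy
re-estimation is attempted — the package consumes segment calls as given.
Degenerate inputs are policed rather than repaired: overlapping segments
and out-of-bounds coordinates are errors; gaps are tolerated; splitting a
segment into identical-copy-number pieces never changes any count
(guaranteed by merge preprocessing, and property-tested).

## Likelihood ratios and evidence points

For each gene the proportion of tumours in an HR category among
germline-positive patients is divided by the proportion among
*BRCA1/2*-negative patients:

LR = p_case / p_ctrl, with p = x / n per group.

When either count is zero a Haldane continuity correction adds 0.5 to all
four implicit 2×2 cells (numerators and, twice, denominators); this is
the unique simple rule that reproduces the published degenerate estimates
and their intervals. The 95% confidence interval is the Katz log-scale
Wald interval, exp(ln LR ± 1.96·SE) with

SE² = (1 − p_case)/(n′_case·p_case) + (1 − p_ctrl)/(n′_ctrl·p_ctrl),

where n′ are the corrected denominators. Coverage of this interval is
property-tested against simulation (≥ 90% over 1,000 random tables) and
its endpoints against a 10,000-replicate parametric bootstrap.

Evidence conversion uses the Bayesian adaptation of the ACMG/AMP
framework: with odds of pathogenicity 350 corresponding to Very Strong
evidence, the tier thresholds are 350^(1/8) (Supporting, ±1), 350^(1/4)
(Moderate, ±2), 350^(1/2) (Strong, ±4) and 350 (Very Strong, ±8),
mirrored at their reciprocals on the benign side; boundaries are
inclusive on the more extreme side. An LR between the Supporting bounds
is Indeterminate (0 points). When the confidence interval contains 1, an
LR that would otherwise carry evidence is downgraded to "Not significant"
(0 points); this CI gate is on by default and can be disabled.

One published number deserves a note: the *BRCA1* subtype-stratified LR
is printed as 23.65 with interval (8.64, 21.57) — a point estimate
outside its own interval. The counts behind that row (27/27 vs 17/232)
give 13.65 under the method above, with exactly the printed interval and
the printed Moderate (+2) assignment (23.65 would have been Strong). The
package reports the internally consistent 13.65.

The sensitivity reanalysis moves Excluded patients who carry a *BRCA1/2*
P/LP variant into the corresponding case group and refits. Whether the
remaining Excluded patients should join the negative controls is not
decidable from the published description; the default keeps them out, and
`include_excluded_controls = TRUE` gives the other behaviour.

The per-VUS report applies the calibration row matching each *BRCA1/2*
VUS carrier's tumour: an HRP tumour contributes the benign-direction row,
an HRD tumour with the gene-concordant subtype contributes the
pathogenic-direction stratified row, and an HRD tumour whose subtype
names the *other* gene contributes nothing towards pathogenicity
(discordant, 0 points). An undetermined subtype falls back to the
dichotomous HRD row with the concordance flag unset.

## The synthetic cohort generator

No patient-level data ship with the package; the generator produces
cohorts with the structure the analysis assumes. Its defaults are the
study conditions: 350 patients split 27 / 21 / 232 / 62 / 8 across the
five groups; P(HRD | group) of 1.00, 19/21, 35/232, 18/62 and 6/8;
subtype distributions among HRD tumours per group (all *BRCA1*-positive
tumours *BRCA1*-type; 2:17 among *BRCA2*-positives; 17:15:3 among
negatives); mean tumour purity 0.58; and the published ER-negative and
grade-3 frequencies for the three analysis groups (24/27 and 19/27,
2/21 and 12/21, 73/232 and 66/232). PR and HER2 negativity rates and the
marker rates of the Excluded/VUS groups are not published; the defaults
(PR− tracking ER− direction per group, HER2− at 0.85–0.90, Excluded/VUS
matching the negative group) are one-time realistic choices that feed
only the association module.

Fixture mode allocates exact counts deterministically, so the fixture
cohort pushed through curation, HR calling and calibration reproduces the
published table cell for cell — that is the package's end-to-end test.
Stochastic mode draws group sizes (multinomially, when group
probabilities are supplied), HR status, subtypes, pathology and scores at
the configured rates. Scores are threshold-consistent draws — uniform on
the correct side of each tool's cutoff — not attempts at realistic score
distributions: no per-group score distributions are published, and the
calibration consumes only the dichotomised calls. Passing tests therefore
demonstrate the correctness of the pipeline's logic under the configured
conditional rates, not robustness to realistic score noise, borderline
calls, or cross-tool discordance (in the fixture all tools agree by
construction; the published cohort had five discordant samples).

The segment simulator builds whole-genome tilings over a toy genome
(22 chromosomes, 240 Mb tapering to 60 Mb, 4 Mb centromeres at 40–50% —
real reference coordinates are intentionally not used): HRD profiles
carve an interstitial 16–25 Mb LOH segment and a ≥ 12 Mb telomeric
imbalance into every chromosome (plus a balanced 2+2 telomeric block on
half of them), guaranteeing a scar sum ≥ 44 by construction; HRP profiles
place a single event on ~8% of chromosomes, keeping the expected sum
under 10. The generator/scorer agreement check (> 0.95 over 400 profiles)
is thus a consistency test of the two modules' conventions, not a claim
about real copy-number data.

## Numerical and testing choices

Internal computation is at full precision; tables display LRs, intervals
and proportions at 2 decimals. The rank-sum test enumerates all rank
assignments exactly (valid under midrank ties) when both samples have ≤ 8
observations — `choose(16, 8)` = 12,870 assignments — and otherwise uses
the tie-corrected normal approximation with a 0.5 continuity correction,
which keeps exact and approximate p-values within 0.02 at the crossover.
Chi-square tests are uncorrected Pearson by default, with Cramér's V as
sqrt(chi² / (n·(min(r,c) − 1))). Scar counters are verified against
independent brute-force scanners on 500 random small profiles (≤ 8
segments per chromosome, 1–3 chromosomes); simulator rate recovery uses
2,000 patients per group against exact binomial 99% intervals; interval
coverage uses 1,000 random two-group tables. These problem sizes keep the
full suite under a minute while leaving the Monte-Carlo margins wide.

## A worked example

```{r example, eval = FALSE}
cohort <- fixture_cohort()
partition <- partition_cohort(curate_variants(cohort$variants),
                              cohort$samples)
calls <- call_hr(cohort$scores, "CHORD")
fit <- hr_calibration(partition, calls, tool = "CHORD")
fit
coef(fit)
confint(fit)
vus_evidence_report(curate_variants(cohort$variants), partition, calls,
                    calibration = fit)
```

## Known limitations

* The calibration is only as good as the group assignment: curation here
  is a transparent collapse of ClinVar/frequency annotations, not a full
  expert-panel rule engine.
* The CHORD undetermined-subtype rule is a surrogate for the classifier's
  internal behaviour.
* Scar sub-score parameters are field conventions, not a byte-exact
  reimplementation of any single published pipeline; ploidy-aware
  imbalance is not implemented.
* The simulator guarantees dichotomised calls, not realistic score
  shapes, cross-tool discordance, or FFPE artefacts.
* Association statistics on synthetic cohorts exercise the machinery;
  the published correlation magnitudes require the real cohort's marker
  data and are out of scope.
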