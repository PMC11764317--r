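---
title: "Somatic deletions, homopolymer context and gene-set interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic deletions, homopolymer context and gene-set interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindel)
```

## The analysis

`skindel` implements a complete analysis of somatic small deletions (DELs)
in non-melanoma skin cancer (NMSC) from matched tumour/blood targeted
sequencing, together with the expression consequences of carrying them in
arsenic-exposed patients. The pipeline has six stages, each usable on its
own:

1. **Somatic filtering.** A tissue call is somatic when its identity key
   (chromosome, start, end, reference allele, alternate allele) does not
   occur among the same patient's blood calls. Matching is exact, not
   positional: two deletions at the same start with different lengths are
   different variants. QC keeps calls with coverage >= 10 reads, variant
   count >= 2, variant allele frequency >= 2% and average call quality
   >= Q60; all boundaries inclusive.
2. **DEL classification.** Unique deletion coordinates observed in tumour
   and in healthy skin are partitioned into tumour-only, shared and
   healthy-only classes, with patient-level event tallies per class; the
   same partition is computed at the gene level. Subtype-associated DELs
   (seen in at least one BCC — or SCC — case and in no healthy-skin sample)
   define the patient-by-gene carrier matrix: a patient carries a gene's
   DEL when they have at least one associated deletion mapped to it.
3. **Homopolymer context.** Each deletion is annotated with the maximal run
   of identical reference bases containing its span. A deletion is "in" a
   homopolymer when its deleted bases are all one base and that run is at
   least `min_run` long.
4. **Expression preparation.** Raw gene counts become counts per million
   (CPM), then `log2(CPM + pseudocount)`.
5. **Gene-set interaction model** (the core estimator, below).
6. **Co-occurrence.** Two binary patient-level mutation statuses are
   cross-tabulated and tested with a two-sided Fisher exact test.

## The gene-set ANOVA

For one gene set, the response is the log2 CPM of every set gene in every
tissue sample (tumour samples of one subtype plus all healthy-skin
controls), modelled jointly by ordinary least squares:

$$y = \mu + T + G + T{\times}G + T{\times}M + \varepsilon,$$

where $T$ is tissue (0 = healthy skin, 1 = tumour), $G$ the gene factor,
$M$ the DEL carrier status of the sample's patient in the target gene
(0/1), and $\varepsilon$ i.i.d. mean-zero noise with a single pooled
variance. With an exposure threshold the model extends to

$$y = \mu + T + G + T{\times}G + T{\times}M + T{\times}A +
T{\times}M{\times}A + \varepsilon,$$

with $A$ the arsenic stratum (0 = low, 1 = high urinary arsenic-creatinine
ratio, UACR). Assumptions worth stating plainly:

* **Healthy controls are a common reference.** Controls are independent
  patients; carrier status is undefined for them, so $M = 0$ by
  construction and the $T{\times}M$ test compares the tumour shift of
  carriers against non-carriers over shared controls.
* **No arsenic main effect.** Exposure enters only through its interaction
  with tissue, so the four tumour subgroups (carrier status crossed with
  exposure stratum) are each contrasted against the pooled healthy mean.
  Controls still carry their own UACR stratum, which matters only in the
  optional stratified mode (below).
* **One error variance.** Variance is pooled across the set's genes and
  samples. Gene-to-gene baseline differences are absorbed by $G$ and
  $T{\times}G$, but gene-specific variances are not modelled, and rows are
  treated as independent — there is no per-sample random effect. Interaction
  p-values therefore benefit from the full gene-by-sample row count and
  should be read as descriptive of this model, not of a mixed-model
  analysis.

The reported effect per stratum is the estimated marginal contrast: the
tumour-minus-healthy difference in mean log2 CPM averaged with equal
weights over the set's genes, with a t-based 95% CI on the residual degrees
of freedom. Estimates and CI bounds are converted to *signed fold changes*:
$2^d$ for $d \ge 0$ and $-2^{-d}$ for $d < 0$, so halving reads as $-2$,
$d = 0$ maps to 1 exactly, and an interval straddling the null prints like
"(-1.20 to 1.12)". The interaction test is the extra-sum-of-squares F test
of the named term; across a screen of many gene sets, interaction p-values
are Bonferroni-adjusted by the number of sets tested.

```{r model-example, eval = FALSE}
co <- generate_cohort(cohort_truth(seed = 7))
report <- run_del_pipeline(pipeline_config_from_cohort(co))
report$screen$APC        # per-set stratum FCs, CIs, interaction p
```

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_coverage` | 10 | reads | targeted-panel low-frequency calling floor |
| `min_count` | 2 | reads | two supporting reads per call |
| `min_frequency` | 2 | % VAF | below this, indistinguishable from noise |
| `min_quality` | 60 | Phred-like | Q60 call-quality cut |
| `min_run` | 3 | bases | shortest tract treated as a homopolymer; observed somatic-deletion tracts start at run 3 |
| `exposure_threshold` | 192 | ug/g UACR | cohort median; low stratum is `<= 192`, high is `> 192` |
| `pseudocount` | 1 | CPM | makes zeros finite; log2(CPM+1) is explicit, not hidden |

All are arguments, not constants. The threshold convention is inclusive
("minimum x" means `>= x`); the exposure convention places the boundary
value in the low stratum.

## What the synthetic cohort emulates

`generate_cohort()` realizes a `cohort_truth()` and records everything it
plants, so every stage can be tested against ground truth. Defaults mirror
the study conditions: 26 BCC + 6 SCC cases and 16 independent healthy-skin
controls, each with a matched blood sample; UACR log-normal with median 192
ug/g (the dichotomization threshold is the population median by
construction, sdlog 0.8 giving a realistic right-skewed exposure spread);
65% of somatic DEL coordinates inside homopolymer tracts of run 3-25
(matching the observed coordinate-level fraction, 404/617); an APC carrier
fraction of 10/26; ns-SNV co-occurrence probabilities of 0.8 given carrier
and 0.25 given non-carrier (reproducing the published 2x2 margins in
expectation); and per-stratum gene-set fold changes taken from the
published four-subgroup tables, alongside a no-interaction control set with
a uniform two-fold tumour shift.

Counts are produced by drawing true log2 CPM (gene baseline + stratum
shift + `N(0, sigma^2)` noise, sigma = 1), scaling `2^y` to a log-normal
library size (median 5e6 reads, a realistic 3'-tag depth) and rounding.
Germline calls are planted identically in tissue and blood, so subtraction
must remove exactly them; QC-failing calls are planted as separate *decoys*
(each violating exactly one threshold) while true somatic events always
pass, so the filter's effect is exactly recoverable rather than
probabilistic.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing-error and mapping artefacts (decoys
are stylized), mutational signatures and transcript-level biology, library
composition effects beyond CPM (no TMM-style normalization is applied, by
design), per-gene variance heterogeneity, and correlation between genes
within a sample. The count round trip does introduce the one distortion
real CPM data has: expression shifts are mildly compositional (an
up-regulated set deflates all other genes' CPM in that sample). With the
default 1030-gene transcriptome this distortion is ~0.05-0.1 log2 units;
calibration tests therefore simulate at the model-table level
(`simulate_model_table()`), where the planted contrast is exact, while
pipeline-level tests allow for the compositional term.

## Numerical and design choices

* **Fitting** is `stats::lm` with treatment coding; aliased columns (e.g.
  `tissue:mut` when no sample carries a DEL) are dropped with a message,
  and contrasts touching aliased columns error rather than silently
  returning 0. Tests hold the fit to a direct normal-equations solve at
  1e-8 relative tolerance.
* **Interaction F** is computed by refitting without the term's design
  columns and forming the extra-sum-of-squares ratio; for a one-column term
  this equals the squared t statistic exactly.
* **Fisher exact p** is the probability-ordering two-sided definition: the
  sum of hypergeometric probabilities (log-space `dhyper`) of all tables
  with the observed margins whose probability is at most the observed
  one, with 1e-7 relative slack on the comparison to absorb rounding.
  Because which exact-test variant lies behind a reported co-occurrence
  p-value is often unstated, Pearson chi-square without continuity
  correction is available as an option; both round to 0.01 on the worked
  2x2 example.
* **Deletion identity** includes the deleted sequence, and VCF anchor bases
  are stripped on import, so TSV- and VCF-derived keys are directly
  comparable and key sets sort deterministically (chromosome lexicographic,
  then start, end, sequence). Gene assignment uses the interval containing
  the deletion's start.
* **Joint vs stratified fits.** Whether per-stratum fold changes should
  come from one joint model or separate per-stratum fits is genuinely open;
  the joint model is the default (one shared error variance, one residual
  df), with `stratified = TRUE` in `run_pathway_screen()` fitting each
  exposure stratum against its own (or pooled) controls for comparison.
* **Homopolymer runs** are measured on the pre-deletion reference,
  extending from the deleted span in both directions in 64-base windows so
  long tracts never truncate; a deletion adjacent to, but not composed of,
  a tract base does not count as homopolymeric.

## Verification sizes

The test suite and acceptance script size their simulations for a
single-CPU desk run: 100 random small instances for the OLS oracle, 200
replicates at 40 tumour samples per stratum (sigma = 1, 10 genes) for CI
coverage and bias of the stratum contrasts, 2000 replicates of a null
cohort (equal shifts in all strata, 6 tumour samples per stratum, 4 genes)
for the size of the three-way interaction test, a 10 kb reference scanned
at every position against a run-length-encoding oracle, and three full
synthetic cohorts for the end-to-end pipeline checks. These finish in a few
minutes total; all reported numbers are recomputed at run time.

## Known limitations

* The homoscedastic, rows-independent error model makes interaction
  p-values optimistic relative to a per-sample mixed model; ranking and
  effect estimates are unaffected.
* Gene-level carrier status collapses all associated DELs in a gene; allele
  fraction and per-variant effects are out of scope.
* The gene map assigns a deletion by its start position only; deletions
  spanning interval boundaries map to the left interval.
* Public-database germline filtering is represented by an optional
  user-supplied exclusion key list, not a bundled database.
* With realistic cohort sizes (26 cases split 11/6/5/4 across subgroups)
  the three-way interaction test has limited power for moderate
  interactions; the screen reports honest wide CIs in the small strata.
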