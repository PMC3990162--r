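---
title: "Methods: copy-number progression analysis for sequential premalignant lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number progression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaprog)
```

## The problem

Oral leukoplakia is a potentially malignant lesion: a fraction of patients
progress, through increasing grades of dysplasia, to invasive oral squamous
cell carcinoma (OSCC) at the same site, while others never do. If the somatic
copy-number alterations (CNAs) that drive progression are already present in
early, low-grade lesions, they are candidate markers for triaging patients.
The analytic strategy implemented here contrasts two arms of an
array-CGH cohort:

* **progressive** lesion series — sequential biopsies from one patient and
  site, ordered by date, walking up the grade ladder
  (non-dysplastic → mild → moderate → severe dysplasia / carcinoma *in situ* →
  invasive carcinoma), ending in an OSCC;
* **non-progressive** leukoplakia from patients who did not develop carcinoma.

CNAs common to the progressive arm but absent from the non-progressive arm,
and recurring along a patient's sequential series, are the progression
candidates. `cnaprog` implements this pipeline end to end, together with a
seeded synthetic-cohort generator that carries a per-sample truth set, so
every stage can be tested quantitatively.

## Data model and conventions

All intervals are 0-based half-open `[start, end)` on `"chr"`-prefixed
autosome labels; sex chromosomes are rejected at ingest (the analysis design
excludes them), and bare labels such as `"1"` are normalized on read. Probe
positions are treated as 1-bp point intervals; a segment spans from its first
probe's position to its last probe's position + 1. Cytogenetic bands are
display decoration only (`annotate_bands()` with a user-supplied UCSC-layout
cytoband file); the unit of analysis is always the coordinate interval, and
the genome build is carried as opaque metadata.

Interval matching throughout the pipeline uses **reciprocal overlap**,
`min(|a∩b|/|a|, |a∩b|/|b|)`, the community-standard symmetric criterion for
CNV/CNA matching. The default threshold is 0.5 at every stage that matches
intervals (population-CNV filtering, group subtraction, region clustering,
truth matching); the source analysis never states its overlap rule, so one
configurable convention is used everywhere rather than per-stage ad-hoc
rules.

## Segmentation

`segment_profile()` converts a probe-level log2-ratio profile into segments
per chromosome with a recursive top-down binary splitter:

1. For the current stretch, evaluate every admissible breakpoint (both
   flanks at least `min_markers` probes, and at least 3 for the Welch test)
   and choose the one maximizing the two-sample Welch *t* statistic between
   the flanks, each truncated to at most `flank_window` probes (default 5x
   `min_markers`); leftmost on ties, for determinism.
2. Accept the split iff its Satterthwaite p-value, **Bonferroni-corrected
   for the number of candidate positions**, is below `split_p_threshold`;
   recurse into both children.
3. A bottom-up merge pass then collapses any adjacent pair that fails either
   criterion: Welch `p < split_p_threshold` (unadjusted — a single
   comparison, not a maximized one) **and** signal-to-noise ratio
   `|Δmean| / pooled SD ≥ snr_threshold`, where the pooled SD is the square
   root of the probe-count-weighted average of the two segment variances.

Defaults are the published stringency of the emulated analysis: 10
consecutive markers, `P < 0.001`, SNR cut-off 0.3. The vendor algorithm's
internals are proprietary; this realizes all three published parameters with
standard change-point machinery.

**Why the Bonferroni correction.** The chosen breakpoint maximizes *t* over
~*n* candidate positions, so under the null hypothesis the maximum is about
`sqrt(2 log n)` ≈ 3.3 for *n* = 200 — right at the pointwise `p = 0.001`
threshold. Using the raw pointwise p-value therefore admits spurious splits
at a high rate, and those splits survive the merge pass (their boundaries
were chosen to maximize the difference). Correcting by the candidate count
restores honest behaviour: on profiles of up to 200 probes with at most two
true breakpoints, recovered boundaries match an exhaustive least-squares
change-point oracle to within one probe (verified in the acceptance suite).

**Why the flanks are windowed.** Top-down binary splitting tests one
breakpoint at a time, so with unbounded flanks a short event (say 40
probes) embedded in a 2,000-probe chromosome dilutes its first-split
statistic by the long flank's length (*t* ≈ 4 instead of ≈ 29) and can fail
the corrected threshold — the classic short-event insensitivity that
circular binary segmentation's paired-breakpoint statistic was invented to
fix. Truncating each flank to a local window restores sensitivity without
changing the algorithm's character (the statistic is still a two-flank
Welch *t*), and costs little power against long, low-amplitude changes (a
0.2-log2 shift still yields *t* ≈ 10 at the default window). With the
window in place, implanted-event recall on default synthetic cohorts is
0.98–1.0 across seeds.

**Degenerate inputs.** Noiseless data give zero pooled variance; the
convention is `p = 0` and `SNR = +∞` when the means differ (split retained)
and `p = 1`, `SNR = 0` otherwise. Chromosomes with fewer than `min_markers`
probes yield one unsplit segment.

## Gain/loss calling

`call_segments()` assigns direction by the linear ratio `2^mean_log2`
against a diploid baseline of 1: gain iff above 1.15, loss iff below 0.85,
neutral otherwise. Neutral segments are retained (they are needed for the
partition invariant) and dropped only where a stage requires non-neutral
calls. No integer copy-number estimation is performed; "two copies" is
implicit in the baseline.

## The filtering cascade

1. **Population-CNV filter** (`filter_population_cnvs()`): a call is removed
   iff a catalog variant of the same direction matches it at reciprocal
   overlap ≥ 0.5 and has population frequency above
   `max_population_frequency` (default 0.01). The emulated analysis keeps
   CNAs "very rare or absent" in the general population without quantifying
   rarity; 1% is the conventional rare-variant cap and is configurable.
   Catalog rows without a frequency column are assigned frequency 1: bare
   presence in a population catalog is taken as evidence the variant is
   common enough to remove.
2. **Non-progressive subtraction** (`subtract_group_cnas()`): progressive
   calls matching any post-filter non-progressive call of the same direction
   at ≥ 0.5 reciprocal overlap are removed. Overlap semantics (rather than
   exact region identity) are used; the source narrative does not specify.
3. Both operations partition their input exactly into `kept` and `removed`
   (a conservation invariant asserted in the tests), and report counts that
   are monotone non-increasing along the cascade.

## Recurrent regions and sequential recurrence

`build_recurrent_regions()` single-linkage clusters same-direction calls by
the reciprocal-overlap criterion (candidate pairs via `IRanges`, components
via union-find; a brute-force all-pairs BFS oracle checks equivalence in the
tests). Each cluster becomes one region:

* `interval` — the union span of member calls;
* `minimal_region` — the members' global intersection; when a single-linkage
  chain has an empty global intersection, the fallback is the leftmost
  maximal run at the deepest coverage depth, which always exists and is the
  natural "minimal common region" of the cluster's densest core;
* `frequency` — presence over the denominator group (progressive lesions
  plus their carcinomas by default). Presence of a region in a sample means
  the sample contributed at least one call to the cluster; raw probes are
  not re-queried.

`sequential_recurrence()` classifies each region per progressive patient:
present in an OSCC **and** in at least one lesion with smaller biopsy order
(`in_OSCC_and_preceding_OPML`), present in **every** sample of the series
(`in_all_sequential_samples`), or `other`; a region's cohort-level class is
the strongest across patients. Patients lacking an OSCC sample are skipped
with a warning. `frequency_table()` reports `100 * n_present / n_group` per
region, descending, omitting regions absent from the group.

## Clustering

`build_feature_matrix()` averages probe log2 ratios in 100-kb bins by
default (the desk-scale analog of clustering all probes; bins with no probes
carry 0), or marks bins ±1/0 from calls in `call_indicator` mode.
`cluster_samples()` is agglomerative average-linkage (UPGMA) clustering on
Euclidean distances — backed by `stats::hclust`, whose deterministic
tie-handling replaces the lexicographic tie rule we originally considered;
a hand-rolled UPGMA oracle verifies cophenetic equivalence in the tests.
Features are not standardized by default (the emulated analysis clustered
raw log2 intensities); a flag enables it. `cluster_separation()` cuts at
*k* = 2 and scores the cut against the progressive-vs-control labels with
the adjusted Rand index — the emulated analysis reports separation only
qualitatively ("two main clusters"), and a chance-corrected index makes it
testable.

## Validation statistics

* `delta_delta_ct()`: replicates averaged on the Ct scale, `dCt = Ct_target
  − Ct_reference`, `ddCt = dCt_sample − dCt_calibrator`, relative quantity
  `2^−ddCt`. Amplification efficiency is fixed at 2 per cycle; no
  standard-curve correction.
* `kruskal_wallis()`: tie-corrected H with a chi-square p-value on k − 1
  degrees of freedom (`stats::kruskal.test` underneath); the all-ties
  degenerate case returns H = 0, p = 1.
* `fisher_exact_2x2()`: two-sided by the point-probability rule — the sum of
  hypergeometric probabilities of all margin-consistent tables no more
  probable than the observed one, compared at relative tolerance 1e-12.
  This is the convention that reproduces the published tobacco-association
  p-value of 0.0051 from the 17/19-smokers vs 8/13-never-smokers
  contingency. A zero margin gives p = 1. Mid-p is not used, and no
  confidence interval is constructed (the source quotes "95%CI" without
  reporting one).
* No multiple-testing correction is applied across validated genes,
  mirroring the emulated analysis's raw P < 0.05 rule; this is a documented
  limitation, not a recommendation.

## The synthetic cohort: what it states and what it omits

`cohort_config()` defaults encode the emulated study design:

| parameter | default | why |
|---|---|---|
| progressive patients × lesions | 5 × 5 | 25 progressive samples ending in carcinoma, matching the emulated cohort's design |
| non-progressive / normal | 5 / 3 | five non-progressive lesions as in the design; a small normal group anchors the control cluster |
| array | 4 chromosomes × 2,000 probes, 7 kb spacing | desk-scale stand-in for a 385K tiling array with ~7 kb median spacing; full scale only via config |
| noise_sd | 0.1 (log2) | no per-sample noise estimate is published; 0.1 gives per-probe SNR ≈ 6 for a single-copy gain, typical of good-quality aCGH |
| gain / loss effect | +0.58 / −1.0 log2 | single-copy algebra at diploid baseline: 3/2 and 1/2 copies |
| core CNAs | 6 shared by all progressive samples | the shared progression burden must dominate the patient-specific burden (≤ 4 grade-acquired + 1 private + 2 germline per sample), as in a cohort whose top recurrent regions span half to all of the progressive samples and where dozens of regions are common to all sequential samples |
| grade-acquired | 1 per step, drawn per patient from a shared pool of 8 recurrent progression regions | monotone accumulation with grade; drawing from a cohort-level pool makes acquired regions recur in a subset of patients, reproducing the mid-range cohort frequencies that recurrent non-core regions show — patient-private acquisition instead produces single-patient frequencies and lets patient subclusters dominate the dendrogram |
| gain/loss composition | 80% gains / 20% losses among progression events, fixed | the emulated cohort's stated composition; deterministic assignment (rather than independent draws) keeps every simulated cohort at the stated mix, since an all-gain core draw materially under-weights the shared signal |
| private | 1 per sample | sporadic passenger events |
| germline CNVs | 2 per individual, from a 20-entry catalog with frequencies 0.05–0.35 | exercises the population filter; shared across a patient's lesions as germline variants are |
| event length | 30–50 probes | ≥ 3× the 10-marker segmentation floor, so implanted events are recoverable by design |

Implanted intervals are mutually non-overlapping across all categories, with
at least 20 probes (2× the marker floor) between events so that distinct
alterations are resolvable by construction, and so that subtraction and CNV
filtering act only on their intended targets. Non-progressive samples carry
only germline and private events — consequently the subtraction stage is a
near no-op on the default cohort (its behaviour is tested on dedicated
fixtures instead), which is the price of keeping the truth sets of the two
arms cleanly separated.

The generator deliberately omits: GC/wave artifacts, whole-genome
amplification distortion, allele-specific and subclonal copy number,
non-uniform probe spacing, and a realistic population CNV frequency
spectrum. A green parameter-recovery test therefore establishes that the
pipeline recovers clean, well-separated single-copy events under iid
Gaussian noise at the stated design — not that it would do so on raw
clinical arrays.

## Numerical choices

* Breakpoint ties: leftmost maximal statistic (determinism).
* Zero-variance segments: see segmentation conventions above.
* `mean_log2` is the plain arithmetic mean of member probes (asserted to
  1e-9 in the tests); BED scores round it to 3 decimals (`×1000`).
* Region construction and subtraction are order-invariant (set semantics),
  asserted by permutation tests.
* Seeds: `simulate_cohort()` seeds the global RNG once from `config$seed`;
  `simulate_patient_series()` uses the current RNG state, so standalone
  calls should be preceded by `set.seed()`.

## Limitations

* Binary splitting's short-event insensitivity (above).
* The local (adjacent-segment) SNR is one reading of the published
  "signal-to-noise ratio cut-off"; a global-noise reading is possible and
  would merge less aggressively.
* One non-neutral segment is counted as one change call; the alternative
  reading (one merged region per chromosome event) would change cohort
  counts but not the region-level conclusions.
* The "regions with no known genes" exclusion is applied only when a gene
  annotation BED is supplied; no annotation ships with the package.
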