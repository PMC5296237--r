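---
title: "Methods: quantifying mood variability from daily and weekly self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mood variability from daily and weekly self-reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodvar)
```

## The analysis problem

Mood disorders are increasingly monitored with ecological momentary
assessment: a short daily questionnaire answered on a phone, alongside
standard clinical instruments answered weekly. Two sampling rates raise
three methodological questions that this package operationalises:

1. **Do people keep answering?** Adherence under explicit completion-window
   rules, over many months.
2. **Does the compact daily instrument measure the same constructs as the
   validated weekly ones?** Latent structure of the daily items and their
   association with weekly scores, after aligning the two sampling rates.
3. **Does day-to-day *variability* carry diagnostic information that
   weekly levels do not?** Scalar variability statistics computed per
   participant and compared across cohorts.

The daily instrument has six items (anxious, elated, sad, angry, irritable,
energetic; Likert 1–7). The weekly battery is ASRM (mania, 0–20), QIDS-SR16
(depression, 0–27 via nine clinical domains), GAD-7 (anxiety, 0–21) and the
EQ-5D VAS (quality of life, 0–100).

## Scoring and banding

Totals are item sums, except QIDS, where the sixteen items collapse to nine
domains first: the four sleep items, the four appetite/weight items and the
two psychomotor items each contribute the *maximum* of their block, the
other six domains are single items, and the total is the domain sum. This
is the standard self-report scoring rule; it matters because the item-level
sum would double-count the mutually exclusive sleep and appetite items.

Banding follows the published cut-offs: the ASRM manic-episode flag at 5.5
(so integer totals of 6 and above are flagged — the boundary can never be
attained exactly on integer totals); QIDS 0–5 normal, 6–10 mild, 11–15
moderate, 16–20 severe, 21–27 very severe; GAD-7 thresholds at 5, 10 and 15,
which imply band upper edges of 4, 9 and 14 (the edges are implied, not
independently published). Validators reject out-of-range or non-integer
items naming the item, so malformed data fail early rather than silently.

## Adherence

Every enrolment day counts as a daily prompt; a day is adherent if a daily
record exists for that calendar date. Weekly prompts follow a fixed weekday
schedule; a prompt is satisfied by a record dated within two days before or
after it. Because responses can drift, each record may satisfy at most one
prompt: records are matched greedily in date order to the nearest unmatched
prompt, ties to the earlier prompt. Cohort adherence over time uses tumbling
(non-overlapping) windows of 30 days by default, summarised by median and
IQR; participants contribute only windows that fit inside their enrolment.
Tumbling rather than rolling windows keep the per-window observations
disjoint, which makes the binomial calibration checks exact.

## Daily-to-weekly alignment

A weekly rating nominally describes the preceding week, so the default
alignment summarises the daily items over the seven calendar days strictly
before the rating date, `[t−7, t−1]`. Three variants probe that assumption:
the median over the same window, the last three days `[t−3, t−1]`, and the
same-day record only. The rating day is excluded from the week windows by
default so that `same_day` remains a genuinely distinct hypothesis; an
`include_rating_day` switch restores the inclusive reading, since published
descriptions rarely say which was used. Days missing inside a window are
simply absent from the summary — no imputation — and a weekly record with no
qualifying daily data is dropped and counted.

## Latent structure

The six daily items are pooled across all participants and
eigendecomposed: covariance matrix by default, because the items share one
1–7 scale (a correlation-matrix option exists; published loading tables are
often consistent with either). Components are ordered by eigenvalue and
signed so that each component's dominant loading is positive, which makes
the negative-affect score increase with sadness/anxiety and the
positive-affect score with elation/energy. Factor scores are centered item
vectors projected on the loadings; the first three are labelled MZneg,
MZpos, MZirr. Pooled raw records (not participant means, no within-person
demeaning) are used, matching the convention of reporting a single loading
matrix for a study.

Per-cohort stability refits the PCA within each cohort and reports the
Tucker congruence φ (absolute cosine between loading vectors) of each
pooled component against its best-matching within-cohort component, greedy
over unmatched components with ties broken by component order. The absolute
value is taken because component signs are arbitrary.

## Variability statistics

For an observed series $x_1..x_N$ in date order:

* standard deviation with the usual $N-1$ denominator;
* mean Teager–Kaiser energy operator,
  $\mathrm{TKEO} = \frac{1}{N}\sum_{i=2}^{N-1}\left(x_i^2 - x_{i-1}x_{i+1}\right)$;
* Shannon entropy of the empirical distribution of distinct observed
  values, $-\sum_j p_j \log p_j$, natural log by default (configurable;
  with ordinal totals of ≤ 28 levels the natural-log maximum is
  $\ln 28 \approx 3.3$, the right order of magnitude for published
  entropies of depression totals);
* RMSSD $= \sqrt{\frac{1}{N}\sum_{i=1}^{N-1}(x_{i+1}-x_i)^2}$.

Three numerical conventions deserve a note. First, the interior
Teager–Kaiser term is $x_i^2 - x_{i-1}x_{i+1}$; a variant that squares the
following sample instead ($x_i^2 - x_{i+1}^2$) circulates in print but
telescopes to a boundary difference $(x_2^2 - x_N^2)/N$ and is not an
energy operator — it is available behind `variant = "printed"` for audit
only. Second, the $1/N$ normalisers in TKEO and RMSSD run over $N-2$ and
$N-1$ terms respectively; they are kept exactly as conventionally printed
rather than "corrected", so values are directly comparable with published
tables. Third, the mean TKEO is *not* exactly translation invariant:
shifting the series by $c$ changes it by the boundary term
$c\,(x_2 - x_1 + x_{N-1} - x_N)/N$, vanishing at rate $1/N$; the test suite
asserts this identity rather than pretending exact invariance.

Gaps: successive observed records are treated as adjacent regardless of the
calendar gap, because self-report studies typically state no gap rule. An
optional `max_gap` splits a series where consecutive records are more than
that many days apart and pools the interior terms across segments (still
normalising by the total $N$). Series too short for a statistic (fewer than
2 observations for std/RMSSD, 3 for TKEO) yield `NA` cells with an explicit
reason rather than errors, so one sparse participant cannot abort a cohort
table.

## Inference

Spearman ρ is the Pearson correlation of mid-ranks (average ranks on ties —
essential for Likert data). The p-value is exact by full permutation
enumeration for n ≤ 9 and uses the large-sample t approximation otherwise.
Association tables pool aligned pairs across participants — one coefficient
per (weekly variable, daily variable) cell — rather than averaging
within-person coefficients; flags mark |ρ| ≥ 0.3 (the conventional
"statistically strong" guideline in medical applications) and p < 10⁻⁴.

Group comparisons use per-participant summary values (medians of score
series, or variability-profile cells), cohort median ± IQR (type-7
quantiles), and two-sided Wilcoxon rank-sum tests for every cohort pair:
exact null distribution when the combined sample is ≤ 20 and tie-free,
normal approximation with tie and continuity corrections otherwise. No
multiple-testing correction is applied, matching how such tables are
conventionally reported; the number of tests is attached as an attribute so
readers can apply their own.

## The synthetic cohort generator

Real clinical mood-monitoring data can rarely be shared, so the package
carries a seeded generator whose output exercises every analysis stage. It
is a test harness with known ground truth, not a scientific model of mood.

Each participant is driven by latent daily AR(1) processes on the 1–7 item
scale: negative affect $z^{neg}$, positive affect $z^{pos}$, and an
irritability-specific residual $z^{irr}$ (mean zero). Items are affine maps
plus independent Gaussian item noise, rounded and clipped to 1–7: anxious
and sad carry $z^{neg}$; elated and energetic carry $z^{pos}$; angry and
irritable carry $s\,z^{neg} + z^{irr}$ where $s$ is the cohort's
`irritability_share`. The separate irritability latent is essential: if
angry/irritable carried only a scaled copy of $z^{neg}$, the four negative
items would span a rank-one signal and the third principal component would
be pure item noise, so no cohort ordering of its variability could exist.
Weekly responses are generated on prompt days from the mean latent over the
preceding seven days — deliberately matching the alignment assumption, so
alignment methods can be benchmarked against known ground truth — with QIDS
and GAD-7 increasing in negative affect, ASRM in positive affect and the
EQ-5D VAS decreasing in negative affect. Daily and weekly records are then
dropped independently at the configured missingness probabilities, and
retained weekly responses are jittered by a uniform integer offset in
−2..+2 days (clamped to the enrolment window).

The default presets define the study conditions: three cohorts (HC, BD,
BPD) of 30 participants followed for 270 days with 15% missingness
(≈ 85% adherence). Negative-affect mean (2.0 / 3.2 / 4.2 on the 1–7 scale)
and innovation sd (0.5 / 0.9 / 1.3), and the irritability latent sd
(0.30 / 0.55 / 0.85), are all ordered HC < BD < BPD, while the share routed
from negative affect to the irritability items falls (0.90 / 0.75 / 0.60) —
so the irritability component's *level* drops from HC to BPD while its
*variability* rises, the qualitative pattern reported for these diagnoses.
The AR coefficient is 0.5 (moods persist over days but decorrelate within a
week) and daily item noise has sd 0.7, roughly one Likert step. These
values were fixed once from this variance algebra; the package makes no
claim that the generated medians match any particular real cohort —
orderings and correlation structure, not levels, are the reproduction
target.

Determinism: each participant's seed is a 31-bit polynomial hash of the
master seed and the cohort label plus participant index, so a fixed
configuration reproduces byte-identical CSVs and adding participants or
cohorts never perturbs earlier ones.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: episodic mood structure (weeks-long depressive
or manic episodes), medication effects, weekday/seasonal cycles,
informative (mood-dependent) missingness, response styles and scale anchors
drifting over time, demographic effects, and staggered enrolment. Passing
tests show the *pipeline* recovers known structure; they are not clinical
validation.

## Problem sizes in the test suite

Unit and property tests run on small cohorts (3–12 participants, 30–150
days) where brute-force oracles are feasible: each variability statistic is
checked against an independently coded loop implementation on 1,000 random
short series to 10⁻¹²; rank-sum p-values against full permutation
enumeration for all group sizes up to 6; Spearman p against permutation
enumeration up to n = 7. The qualitative cohort-structure checks run the
full presets (30 participants per cohort, 270 days) across 20 master seeds
and require the orderings and significance in at least 19 of 20.

## Known limitations

* The alignment assumes calendar dates; time-of-day and timezone effects
  are out of scope.
* Variability statistics ignore calendar gaps unless `max_gap` is set;
  with high missingness RMSSD and TKEO mix 1-day and multi-day transitions.
* Pooled association coefficients conflate within- and between-person
  correlation; with strong cohort separation the pooled ρ is dominated by
  between-person differences.
* Entropy on raw distinct values is sensible for ordinal totals but
  degenerates for continuous scores (every value distinct → log N); bin
  continuous series before profiling them.
* PCA is unrotated; interpretations of components beyond the first two are
  conventional labels, not identified constructs, and the third component's
  instability across cohorts is expected.
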