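# moodvar

Analysis tools for longitudinal mood self-monitoring studies in which
participants answer a compact daily mood questionnaire on a smartphone and a
battery of standard clinical instruments weekly. The package is aimed at
researchers in digital psychiatry who want to quantify *mood instability* —
day-to-day variability of affect — and compare it across diagnostic groups
such as bipolar disorder (BD), borderline personality disorder (BPD) and
healthy controls (HC).

The daily instrument is a six-item questionnaire (anxious, elated, sad,
angry, irritable, energetic; Likert 1–7, "Mood Zoom"). The weekly
instruments are the Altman Self-Rating Mania scale (ASRM, total 0–20), the
Quick Inventory of Depressive Symptomatology (QIDS-SR16, 16 items collapsed
to nine clinical domains, total 0–27), GAD-7 (total 0–21) and the EQ-5D
quality-of-life visual-analogue scale (0–100).

## What the package computes

* **Instrument scoring and clinical banding** — item validation, totals,
  QIDS nine-domain collapse, the ASRM manic-episode flag (cut-off 5.5), and
  the QIDS/GAD-7 severity bands.
* **Adherence** — the proportion of prompts completed: same-day completion
  for the daily questionnaire, completion within ±2 days of the prompt for
  the weekly ones, plus cohort adherence curves over time into the study.
* **Daily→weekly alignment** — summarising daily records over the week
  preceding each weekly rating (mean, median, last-three-days or same-day
  variants) so the two sampling rates can be compared fairly.
* **Latent structure** — PCA of the six daily items; the first three
  components are interpreted as negative affect (MZneg), positive affect
  (MZpos) and irritability (MZirr), with per-cohort Tucker-congruence
  stability checks.
* **Variability statistics** — for a series x_1..x_N, the sample standard
  deviation; the mean Teager–Kaiser energy operator

      TKEO = (1/N) Σ_{i=2}^{N−1} (x_i² − x_{i−1}·x_{i+1})

  the Shannon entropy of the empirical value distribution

      H = − Σ_j p_j log p_j

  and the root mean squared successive differences

      RMSSD = sqrt( (1/N) Σ_{i=1}^{N−1} (x_{i+1} − x_i)² )

* **Inference** — Spearman association matrices between the weekly items /
  totals and the aligned daily items / factors (|ρ| ≥ 0.3 flagged as
  *statistically strong*), and cohort comparison tables (median ± IQR with
  pairwise two-sided Wilcoxon rank-sum tests).
* **Synthetic cohorts** — because real clinical mood-monitoring data
  typically cannot be shared, a seeded generator produces three-cohort
  studies from latent AR(1) affect processes, with cohort-ordered
  negative-affect level and variability (BPD > BD > HC), configurable
  missingness and weekly response jitter, so every stage is testable
  end-to-end.

## Worked example

```r
library(moodvar)

study <- generate_study(default_study_config(seed = 1))
study
#> mz_study: 90 participants (BD n=30, BPD n=30, HC n=30), 20660 daily records, 3015 weekly records

loadings <- fit_mz_pca(study$daily)
loadings
#> Mood Zoom PCA loadings (covariance matrix, n = 20660 rows)
#>              P1     P2     P3     P4     P5     P6
#> anxious   0.602 -0.002 -0.361  0.121  0.700  0.044
#> elated    0.012  0.703  0.031  0.701 -0.114  0.005
#> sad       0.604  0.005 -0.377 -0.111 -0.692 -0.045
#> angry     0.369 -0.025  0.602 -0.021 -0.049  0.706
#> irritable 0.368 -0.027  0.604  0.004  0.038 -0.706
#> energetic 0.012  0.710  0.015 -0.694  0.120 -0.006
#> % variance:    51.1  23.0  11.0   5.5   5.0   4.4
#> % cumulative:  51.1  74.1  85.1  90.6  95.6 100.0

adh <- compute_adherence(study)
sprintf("median daily adherence: %.1f%%, weekly: %.1f%%",
        median(adh$daily_adherence), median(adh$weekly_adherence))
#> "median daily adherence: 85.2%, weekly: 87.2%"

cmp <- comparison_table(summarise_scores(study, loadings))
dplyr::select(cmp, variable, dplyr::starts_with("median"), p_BPD_vs_HC)
#> # A tibble: 7 × 5
#>   variable median_BD median_BPD median_HC p_BPD_vs_HC
#>   <chr>        <dbl>      <dbl>     <dbl>       <dbl>
#> 1 ASRM        1           2         2        6.85e- 3
#> 2 EQ-5D      64          48.2      83        2.85e-11
#> 3 GAD-7       6          10         2        4.74e-12
#> 4 MZirr       0.0647     -0.438     0.181    3.02e-11
#> 5 MZneg       0.189       1.39     -1.73     3.02e-11
#> 6 MZpos      -0.248       0.434    -0.151    8.88e- 6
#> 7 QIDS        9          13         3        1.07e-11
```

Reading the output: the first three principal components explain 85% of the
daily-item variance, splitting into a negative-affect axis (anxious/sad,
with angry/irritable loading more weakly), a positive-affect axis
(elated/energetic) and an irritability contrast. Per-participant median
MZneg scores order BPD > BD > HC, and depression (QIDS), anxiety (GAD-7)
and quality of life (EQ-5D, inverted) separate the clinical groups from
controls with very small rank-sum p-values. `variability_profile()` +
`comparison_table(variability_long(...))` produce the analogous table for
the four variability statistics, where the daily factor series separate BD
from BPD.

`run_pipeline()` (or `run_demo(out_dir, seed)`) executes the whole chain —
generate/read, score, adherence, PCA, alignment, variability, inference —
and writes the report CSVs, a YAML manifest and a log; identical
configurations reproduce byte-identical outputs.

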