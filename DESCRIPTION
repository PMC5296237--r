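Package: moodvar
Title: Longitudinal Mood-Variability Analysis for Daily Self-Monitoring Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ecological momentary assessment studies that
    pair a compact daily mood questionnaire (six Likert 1-7 items: anxious,
    elated, sad, angry, irritable, energetic) with weekly clinical instruments
    (ASRM, QIDS-SR16, GAD-7, EQ-5D VAS). Provides instrument scoring and
    clinical banding, adherence accounting under completion-window rules,
    daily-to-weekly alignment, principal-component extraction of latent mood
    factors, four time-series variability statistics (standard deviation,
    Teager-Kaiser energy operator, Shannon entropy, root mean squared
    successive differences), Spearman association matrices, pairwise Wilcoxon
    cohort comparisons, and a synthetic three-cohort (bipolar disorder,
    borderline personality disorder, healthy control) study generator for
    end-to-end testing when real cohort data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
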