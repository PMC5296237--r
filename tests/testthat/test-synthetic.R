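test_that("generation is deterministic and stable under cohort growth", {
  cfg <- tiny_config(seed = 7)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1$daily, st2$daily)
  expect_identical(st1$weekly, st2$weekly)
  expect_identical(st1$cohorts, st2$cohorts)

  # writing twice gives byte-identical CSVs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(st1, d1); write_study(st2, d2)
  for (f in c("daily.csv", "weekly.csv", "cohorts.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # adding participants never perturbs earlier ones
  cfg_big <- tiny_config(seed = 7, n_participants = 5)
  st_big <- generate_study(cfg_big)
  ids <- unique(st1$daily$participant_id)
  expect_identical(st1$daily,
                   st_big$daily[st_big$daily$participant_id %in% ids, ])
})

test_that("record counts and validity match the configuration", {
  cfg <- tiny_config(seed = 3)
  st <- generate_study(cfg)
  expect_identical(nrow(st$cohorts), 9L)
  expect_setequal(unique(st$cohorts$cohort), c("HC", "BD", "BPD"))
  # all generated values pass the item validators
  for (i in sample(nrow(st$daily), 25)) {
    expect_silent(validate_mz(as.numeric(st$daily[i, mz_items()])))
  }
  for (i in sample(nrow(st$weekly), 10)) {
    expect_silent(score_asrm(as.numeric(st$weekly[i, paste0("asrm_", 1:5)])))
    expect_silent(score_qids(as.numeric(st$weekly[i, paste0("qids_", 1:16)])))
    expect_silent(score_gad7(as.numeric(st$weekly[i, paste0("gad7_", 1:7)])))
    expect_silent(validate_eq5d(st$weekly$eq5d_vas[i]))
  }
  # every record inside the enrolment window
  j <- dplyr::left_join(st$daily, st$cohorts, by = "participant_id")
  expect_true(all(j$date >= j$enrolment_start & j$date <= j$enrolment_end))
})

test_that("zero missingness yields a complete daily stream", {
  cfg <- study_config(list(
    cohort_params("HC", 2, 30, neg_mean = 3, pos_mean = 4,
                  neg_sd = 0.5, pos_sd = 0.5,
                  daily_missing_prob = 0, weekly_missing_prob = 0)),
    seed = 1)
  st <- generate_study(cfg)
  expect_identical(nrow(st$daily), 60L)
  adh <- compute_adherence(st)
  expect_equal(adh$daily_adherence, c(100, 100))
  expect_equal(adh$weekly_adherence, c(100, 100))
})

test_that("empirical missingness matches the configured probability", {
  m <- 0.2
  cfg <- tiny_config(seed = 21, n_participants = 10, n_days = 120,
                     daily_missing_prob = m)
  st <- generate_study(cfg)
  n_prompts <- 30 * 120
  frac_missing <- 1 - nrow(st$daily) / n_prompts
  se <- sqrt(m * (1 - m) / n_prompts)
  expect_lt(abs(frac_missing - m), 3 * se)
})

test_that("increasing neg_sd increases MZneg-series std and rmssd", {
  level_stat <- function(sd_level) {
    cfg <- study_config(list(
      cohort_params("X", 6, 120, neg_mean = 4, pos_mean = 4,
                    neg_sd = sd_level, pos_sd = 0.5,
                    daily_missing_prob = 0, weekly_missing_prob = 0)),
      seed = 31)
    st <- generate_study(cfg)
    ld <- fit_mz_pca(st$daily)
    # fix factor direction: anxious series directly reflects the latent
    per <- dplyr::group_by(
      dplyr::bind_cols(st$daily["participant_id"],
                       factor_scores(st$daily, ld)["MZneg"]),
      participant_id)
    per <- dplyr::summarise(per, std = sd(MZneg),
                            rmssd = series_rmssd(MZneg))
    c(median(per$std), median(per$rmssd))
  }
  stats_by_sd <- vapply(c(0.3, 0.8, 1.4), level_stat, numeric(2))
  expect_true(all(diff(stats_by_sd[1, ]) > 0))
  expect_true(all(diff(stats_by_sd[2, ]) > 0))
})

test_that("invalid configurations are rejected; empty cohorts warn", {
  expect_error(cohort_params("X", 2, 5, 3, 4, 0.5, 0.5), "n_days")
  expect_error(cohort_params("X", 2, 30, 3, 4, 0, 0.5), "sds")
  expect_error(cohort_params("X", 2, 30, 3, 4, 0.5, 0.5, ar_coef = 1),
               "ar_coef")
  expect_error(cohort_params("X", 2, 30, 3, 4, 0.5, 0.5,
                             daily_missing_prob = 1), "daily_missing_prob")
  p <- cohort_params("X", 2, 30, 3, 4, 0.5, 0.5)
  expect_error(study_config(list(p, p)), "unique")
  cfg <- study_config(list(
    cohort_params("EMPTY", 0, 30, 3, 4, 0.5, 0.5),
    cohort_params("X", 1, 30, 3, 4, 0.5, 0.5)), seed = 2)
  expect_warning(st <- generate_study(cfg), "zero participants")
  expect_identical(nrow(st$cohorts), 1L)
})

test_that("weekly responses track the negative latent level across cohorts", {
  st <- tiny_study(n_participants = 6, n_days = 120, seed = 13)
  tot <- dplyr::left_join(weekly_totals(st),
                          st$cohorts[c("participant_id", "cohort")],
                          by = "participant_id")
  med <- tapply(tot$qids_total, tot$cohort, median)
  expect_true(med["BPD"] > med["BD"])
  expect_true(med["BD"] > med["HC"])
  vas <- tapply(tot$eq5d_vas, tot$cohort, median)
  expect_true(vas["HC"] > vas["BD"])
  expect_true(vas["BD"] > vas["BPD"])
})
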