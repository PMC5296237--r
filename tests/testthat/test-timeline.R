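test_that("write then read round-trips a generated study", {
  st <- tiny_study(seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  st2 <- read_study(paths["daily"], paths["weekly"], paths["cohorts"],
                    prompts_csv = paths["prompts"])
  expect_equal(as.data.frame(st2$daily), as.data.frame(st$daily))
  expect_equal(as.data.frame(st2$weekly), as.data.frame(st$weekly))
  expect_equal(as.data.frame(st2$cohorts), as.data.frame(st$cohorts))
  expect_equal(as.data.frame(st2$prompts), as.data.frame(st$prompts))
})

test_that("strict mode rejects malformed rows naming the row; lenient skips", {
  st <- tiny_study(seed = 18)
  dir <- withr::local_tempdir()
  bad <- st
  bad$daily$anxious[4] <- 9L
  paths <- write_study(mz_study(bad$daily, bad$weekly, bad$cohorts,
                                validate = FALSE), dir)
  expect_error(read_study(paths["daily"], paths["weekly"], paths["cohorts"]),
               "daily.*row 4")
  expect_warning(
    ok <- read_study(paths["daily"], paths["weekly"], paths["cohorts"],
                     strict = FALSE),
    "skipped")
  expect_identical(nrow(ok$daily), nrow(st$daily) - 1L)

  # unknown participant
  bad2 <- st
  bad2$weekly$participant_id[1] <- "GHOST"
  paths2 <- write_study(mz_study(bad2$daily, bad2$weekly, bad2$cohorts,
                                 validate = FALSE), withr::local_tempdir())
  expect_error(read_study(paths2["daily"], paths2["weekly"], paths2["cohorts"]),
               "unknown participant")
})

test_that("an empty weekly file yields empty weekly streams with a warning", {
  st <- tiny_study(seed = 19)
  dir <- withr::local_tempdir()
  st$weekly <- st$weekly[0, ]
  st$prompts <- NULL
  paths <- write_study(st, dir)
  expect_warning(st2 <- read_study(paths["daily"], paths["weekly"],
                                   paths["cohorts"]),
                 "no records")
  expect_identical(nrow(st2$weekly), 0L)
})

test_that("daily adherence is the same-day completion percentage", {
  start <- as.Date("2021-03-01")
  st <- manual_study(daily_dates = start + sort(sample(0:29, 24)),
                     start = start, n_days = 30)
  adh <- compute_adherence(st)
  expect_equal(adh$daily_adherence, 80)
  expect_equal(adh$n_days, 30L)
  # deleting a record can only lower it
  st2 <- st
  st2$daily <- st2$daily[-1, ]
  expect_lt(compute_adherence(st2)$daily_adherence, 80)
})

test_that("weekly adherence honours the +/- 2 day window and greedy matching", {
  start <- as.Date("2021-03-01")  # a Monday
  # prompts every Monday for 4 weeks
  answered <- function(record_dates) {
    st <- manual_study(daily_dates = start, weekly_dates = record_dates,
                       start = start, n_days = 28)
    st$prompts <- tibble::tibble(participant_id = "P1",
                                 date = start + c(0, 7, 14, 21))
    compute_adherence(st)$weekly_adherence
  }
  expect_equal(answered(start + c(2, 7)), 50)        # +2 days counts
  expect_equal(answered(start + c(3, 7)), 25)        # +3 days does not
  expect_equal(answered(as.Date(character(0))), 0)   # nothing answered
  expect_equal(answered(start + c(0, 7, 14, 21)), 100)
  # two records near one prompt satisfy at most that single prompt
  expect_equal(answered(start + c(6, 8)), 25)
})

test_that("adherence curve is flat at 100% under full adherence", {
  cfg <- study_config(list(
    cohort_params("HC", 3, 90, neg_mean = 3, pos_mean = 4,
                  neg_sd = 0.5, pos_sd = 0.5,
                  daily_missing_prob = 0, weekly_missing_prob = 0)),
    seed = 4)
  st <- generate_study(cfg)
  curve <- adherence_curve(st, window_days = 30)
  expect_identical(nrow(curve), 3L)  # 90 days -> 3 tumbling windows
  expect_equal(curve$median_adherence, rep(100, 3))
  expect_equal(curve$iqr_adherence, rep(0, 3))
})

test_that("adherence curve recovers the configured missingness", {
  m <- 0.15
  cfg <- tiny_config(seed = 23, n_participants = 12, n_days = 120,
                     daily_missing_prob = m)
  st <- generate_study(cfg)
  curve <- adherence_curve(st, window_days = 30)
  # pooled across windows and cohorts: near 100(1-m)% within binomial error
  grand <- mean(curve$median_adherence)
  se <- 100 * sqrt(m * (1 - m) / (30 * 36))
  expect_lt(abs(grand - 100 * (1 - m)), 5 * se)
})

test_that("alignment methods summarise the documented windows", {
  start <- as.Date("2021-03-01")
  t <- start + 10
  items <- matrix(4L, 11, 6)
  items[, 1] <- c(7L, 7L, 7L, 1:7, 7L)  # anxious on days t-7..t-1 is 1..7
  st <- manual_study(daily_dates = start + 0:10, daily_items = items,
                     weekly_dates = t, start = start, n_days = 30)
  for (m in c("mean_prev_week", "median_prev_week", "last3_days", "same_day")) {
    al <- align_daily_to_weekly(st, method = m)
    expect_identical(nrow(al), 1L)
    expected <- switch(m, mean_prev_week = 4, median_prev_week = 4,
                       last3_days = 6, same_day = 7)
    expect_equal(al$anxious, expected)
    expect_equal(al$elated, 4)  # constant series preserved by every method
    expect_identical(al$n_days_used,
                     switch(m, mean_prev_week = 7L, median_prev_week = 7L,
                            last3_days = 3L, same_day = 1L))
  }
  # include_rating_day widens the week window to [t-7, t]
  al <- align_daily_to_weekly(st, "mean_prev_week", include_rating_day = TRUE)
  expect_equal(al$anxious, mean(c(1:7, 7)))
})

test_that("pairs without qualifying daily data are dropped and counted", {
  start <- as.Date("2021-03-01")
  st <- manual_study(daily_dates = start + 0:2,
                     weekly_dates = c(start + 2, start + 20),
                     start = start, n_days = 30)
  al <- align_daily_to_weekly(st, "same_day")
  expect_identical(nrow(al), 1L)
  expect_identical(attr(al, "dropped"), 1L)
  expect_error(align_daily_to_weekly(st, "nearest_day"), "arg")
})

test_that("mean alignment is invariant to daily row order", {
  st <- tiny_study(seed = 29)
  al1 <- align_daily_to_weekly(st, "mean_prev_week")
  st$daily <- st$daily[rev(seq_len(nrow(st$daily))), ]
  al2 <- align_daily_to_weekly(st, "mean_prev_week")
  expect_equal(as.data.frame(al1), as.data.frame(al2))
})

test_that("weekly totals agree with the single-response scorers", {
  st <- tiny_study(seed = 31)
  tot <- weekly_totals(st)
  for (i in sample(nrow(tot), 10)) {
    w <- st$weekly[st$weekly$participant_id == tot$participant_id[i] &
                     st$weekly$date == tot$date[i], ]
    expect_identical(tot$asrm_total[i],
                     score_asrm(as.numeric(w[paste0("asrm_", 1:5)])))
    expect_identical(tot$qids_total[i],
                     score_qids(as.numeric(w[paste0("qids_", 1:16)])))
    expect_identical(tot$gad7_total[i],
                     score_gad7(as.numeric(w[paste0("gad7_", 1:7)])))
  }
})
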