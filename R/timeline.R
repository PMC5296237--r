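daily_cols <- function() c("participant_id", "date", mz_items())

weekly_item_cols <- function() {
  c(paste0("asrm_", 1:5), paste0("qids_", 1:16), paste0("gad7_", 1:7),
    "eq5d_vas")
}

weekly_cols <- function() c("participant_id", "date", weekly_item_cols())

empty_daily <- function() {
  tibble::as_tibble(c(list(participant_id = character(0),
                           date = as.Date(character(0))),
                      stats::setNames(rep(list(integer(0)), 6), mz_items())))
}

empty_weekly <- function() {
  cols <- weekly_item_cols()
  vals <- c(rep(list(integer(0)), length(cols) - 1), list(numeric(0)))
  tibble::as_tibble(c(list(participant_id = character(0),
                           date = as.Date(character(0))),
                      stats::setNames(vals, cols)))
}

#' Longitudinal study container
#'
#' Bundles the three long-format tables of a daily/weekly self-monitoring
#' study: daily Mood Zoom responses, weekly instrument responses
#' (ASRM, QIDS, GAD-7, EQ-5D VAS) and per-participant cohort metadata with
#' enrolment windows. Optionally carries the weekly prompt schedule (known
#' for generated data; inferred from the data otherwise).
#'
#' @param daily Tibble: `participant_id`, `date`, six item columns
#'   (see [mz_items()]).
#' @param weekly Tibble: `participant_id`, `date`, `asrm_1..5`,
#'   `qids_1..16`, `gad7_1..7`, `eq5d_vas`.
#' @param cohorts Tibble: `participant_id`, `cohort`, `enrolment_start`,
#'   `enrolment_end`.
#' @param prompts Optional tibble of weekly prompt dates per participant.
#' @param provenance Optional generator configuration echo.
#' @param validate Run the structural validators (default TRUE).
#' @return An object of class `mz_study`.
#' @export
mz_study <- function(daily, weekly, cohorts, prompts = NULL,
                     provenance = NULL, validate = TRUE) {
  daily <- tibble::as_tibble(daily)
  weekly <- tibble::as_tibble(weekly)
  cohorts <- tibble::as_tibble(cohorts)
  obj <- structure(list(daily = daily, weekly = weekly, cohorts = cohorts,
                        prompts = prompts, provenance = provenance),
                   class = "mz_study")
  if (validate) validate_study(obj)
  obj
}

validate_study <- function(study) {
  daily <- study$daily; weekly <- study$weekly; cohorts <- study$cohorts
  for (nm in c("participant_id", "cohort", "enrolment_start", "enrolment_end")) {
    if (!nm %in% names(cohorts)) stop("cohorts table lacks column ", nm, call. = FALSE)
  }
  if (anyDuplicated(cohorts$participant_id)) {
    stop("duplicate participant_id in cohorts table", call. = FALSE)
  }
  miss <- setdiff(names(empty_daily()), names(daily))
  if (length(miss)) stop("daily table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(names(empty_weekly()), names(weekly))
  if (length(miss)) stop("weekly table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (tab in list(daily, weekly)) {
    unknown <- setdiff(unique(tab$participant_id), cohorts$participant_id)
    if (length(unknown)) {
      stop("records for unknown participant(s): ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(tab[c("participant_id", "date")])) {
      stop("duplicate (participant, date) records", call. = FALSE)
    }
  }
  win <- cohorts[c("participant_id", "enrolment_start", "enrolment_end")]
  for (tab in list(daily, weekly)) {
    j <- dplyr::left_join(tab[c("participant_id", "date")], win,
                          by = "participant_id")
    out <- j$date < j$enrolment_start | j$date > j$enrolment_end
    if (any(out)) {
      stop(sprintf("%d record(s) outside the enrolment window", sum(out)),
           call. = FALSE)
    }
  }
  range_bad <- function(x, lo, hi) any(x != round(x) | x < lo | x > hi)
  for (it in mz_items()) {
    if (range_bad(daily[[it]], 1, 7)) {
      stop("daily item '", it, "' outside 1-7", call. = FALSE)
    }
  }
  checks <- list(asrm = c(0, 4), qids = c(0, 3), gad7 = c(0, 3))
  for (pref in names(checks)) {
    for (col in grep(paste0("^", pref, "_"), names(weekly), value = TRUE)) {
      if (range_bad(weekly[[col]], checks[[pref]][1], checks[[pref]][2])) {
        stop("weekly item '", col, "' outside its range", call. = FALSE)
      }
    }
  }
  if (nrow(weekly) && any(weekly$eq5d_vas < 0 | weekly$eq5d_vas > 100)) {
    stop("eq5d_vas outside 0-100", call. = FALSE)
  }
  invisible(study)
}

#' @export
print.mz_study <- function(x, ...) {
  cat(sprintf(
    "mz_study: %d participants (%s), %d daily records, %d weekly records\n",
    nrow(x$cohorts),
    paste(sprintf("%s n=%d", names(table(x$cohorts$cohort)),
                  as.integer(table(x$cohorts$cohort))), collapse = ", "),
    nrow(x$daily), nrow(x$weekly)))
  invisible(x)
}

#' Write a study to long-format CSV files
#'
#' Writes `daily.csv`, `weekly.csv`, `cohorts.csv` and, when the prompt
#' schedule is known, `prompts.csv` into a directory.
#'
#' @param study An `mz_study` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mz_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(daily = file.path(dir, "daily.csv"),
             weekly = file.path(dir, "weekly.csv"),
             cohorts = file.path(dir, "cohorts.csv"))
  readr::write_csv(study$daily, paths["daily"])
  readr::write_csv(study$weekly, paths["weekly"])
  readr::write_csv(study$cohorts, paths["cohorts"])
  if (!is.null(study$prompts)) {
    paths["prompts"] <- file.path(dir, "prompts.csv")
    readr::write_csv(study$prompts, paths["prompts"])
  }
  invisible(paths)
}

read_validated_csv <- function(path, spec_names, strict, label) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(spec_names, names(df))
  if (length(miss)) {
    stop(label, " file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df
}

drop_bad_rows <- function(df, bad, strict, label) {
  if (!any(bad)) return(df)
  rows <- which(bad)
  msg <- sprintf("%s: %d invalid row(s) (first at data row %d)",
                 label, length(rows), rows[1])
  if (strict) stop(msg, call. = FALSE)
  warning(msg, "; rows skipped")
  df[!bad, , drop = FALSE]
}

#' Read a study from long-format CSV files
#'
#' Inverse of [write_study()]. In strict mode (default) malformed rows —
#' out-of-range items, unknown participants, duplicate (participant, date)
#' pairs, records outside the enrolment window — abort with a row-numbered
#' error; in lenient mode they are skipped with a warning.
#'
#' @param daily_csv,weekly_csv,cohorts_csv Paths to the three CSV files.
#' @param prompts_csv Optional path to a prompt-schedule CSV; when absent
#'   the weekly prompt schedule is inferred per participant from the weekday
#'   of the first weekly record (configurable via `prompt_weekday`).
#' @param strict Abort on malformed rows (default) rather than skip them.
#' @param prompt_weekday Optional weekday 0--6 overriding prompt inference.
#' @return An `mz_study` object.
#' @export
read_study <- function(daily_csv, weekly_csv, cohorts_csv,
                       prompts_csv = NULL, strict = TRUE,
                       prompt_weekday = NULL) {
  cohorts <- read_validated_csv(
    cohorts_csv, c("participant_id", "cohort", "enrolment_start", "enrolment_end"),
    strict, "cohorts")
  cohorts$enrolment_start <- as.Date(cohorts$enrolment_start)
  cohorts$enrolment_end <- as.Date(cohorts$enrolment_end)

  daily <- read_validated_csv(daily_csv, daily_cols(), strict, "daily")
  daily$date <- as.Date(daily$date)
  item_m <- as.matrix(daily[mz_items()])
  bad <- rowSums(is.na(item_m) | item_m != round(item_m) |
                   item_m < 1 | item_m > 7) > 0
  daily <- drop_bad_rows(daily, bad, strict, "daily")

  weekly <- read_validated_csv(weekly_csv, weekly_cols(), strict, "weekly")
  weekly$date <- as.Date(weekly$date)
  if (nrow(weekly) == 0) {
    warning("weekly file has no records")
    weekly <- empty_weekly()
  } else {
    lim <- list(asrm = c(0, 4), qids = c(0, 3), gad7 = c(0, 3))
    bad <- rep(FALSE, nrow(weekly))
    for (pref in names(lim)) {
      m <- as.matrix(weekly[grep(paste0("^", pref, "_"), names(weekly))])
      bad <- bad | rowSums(is.na(m) | m != round(m) |
                             m < lim[[pref]][1] | m > lim[[pref]][2]) > 0
    }
    bad <- bad | is.na(weekly$eq5d_vas) | weekly$eq5d_vas < 0 | weekly$eq5d_vas > 100
    weekly <- drop_bad_rows(weekly, bad, strict, "weekly")
  }

  for (nm in c("daily", "weekly")) {
    tab <- get(nm)
    unknown <- !tab$participant_id %in% cohorts$participant_id
    tab <- drop_bad_rows(tab, unknown, strict, paste(nm, "(unknown participant)"))
    dup <- duplicated(tab[c("participant_id", "date")])
    tab <- drop_bad_rows(tab, dup, strict, paste(nm, "(duplicate record)"))
    win <- dplyr::left_join(tab[c("participant_id", "date")],
                            cohorts, by = "participant_id")
    out <- win$date < win$enrolment_start | win$date > win$enrolment_end
    tab <- drop_bad_rows(tab, out, strict, paste(nm, "(outside enrolment)"))
    assign(nm, tab)
  }

  prompts <- if (!is.null(prompts_csv)) {
    p <- read_validated_csv(prompts_csv, c("participant_id", "date"),
                            strict, "prompts")
    p$date <- as.Date(p$date)
    p
  } else {
    infer_prompts(weekly, cohorts, prompt_weekday)
  }
  mz_study(daily[daily_cols()], weekly[weekly_cols()], cohorts,
           prompts = prompts)
}

# Weekly prompt schedule: either a fixed weekday, or per participant the
# weekday of their first weekly record; participants with no weekly records
# fall back to the weekday of their enrolment start.
infer_prompts <- function(weekly, cohorts, prompt_weekday = NULL) {
  rows <- lapply(seq_len(nrow(cohorts)), function(i) {
    pid <- cohorts$participant_id[i]
    start <- cohorts$enrolment_start[i]
    end <- cohorts$enrolment_end[i]
    wd <- if (!is.null(prompt_weekday)) {
      prompt_weekday
    } else {
      first <- suppressWarnings(min(weekly$date[weekly$participant_id == pid]))
      if (is.finite(first)) as.POSIXlt(first)$wday else as.POSIXlt(start)$wday
    }
    tibble::tibble(participant_id = pid,
                   date = weekly_prompt_dates(start, end, wd))
  })
  dplyr::bind_rows(rows)
}

# Greedy matching of weekly records to prompts: records in date order, each
# assigned to the nearest unmatched prompt within +/- window days, ties to
# the earlier prompt. Returns the number of satisfied prompts.
match_weekly_prompts <- function(prompt_dates, record_dates, window = 2) {
  if (length(prompt_dates) == 0) return(0L)
  matched <- rep(FALSE, length(prompt_dates))
  for (rd in sort(as.numeric(record_dates))) {
    d <- abs(as.numeric(prompt_dates) - rd)
    d[matched] <- Inf
    j <- which.min(d)  # first index on ties = earlier prompt
    if (is.finite(d[j]) && d[j] <= window) matched[j] <- TRUE
  }
  sum(matched)
}

#' Adherence under the completion-window rules
#'
#' Daily adherence is the percentage of enrolment days with a same-day Mood
#' Zoom record (every enrolment day is a prompt). Weekly adherence is the
#' percentage of weekly prompts answered by a record dated within two days
#' before or after the prompt; each record satisfies at most one prompt
#' (greedy nearest match, ties to the earlier prompt).
#'
#' @param study An `mz_study` object.
#' @return Tibble with one row per participant: `participant_id`, `cohort`,
#'   `n_days`, `n_prompts`, `daily_adherence`, `weekly_adherence`
#'   (percentages in 0--100).
#' @export
compute_adherence <- function(study) {
  stopifnot(inherits(study, "mz_study"))
  cohorts <- study$cohorts
  if (any(cohorts$enrolment_end < cohorts$enrolment_start)) {
    stop("zero-length enrolment window: adherence undefined", call. = FALSE)
  }
  prompts <- study$prompts
  if (is.null(prompts)) prompts <- infer_prompts(study$weekly, cohorts)
  rows <- lapply(seq_len(nrow(cohorts)), function(i) {
    pid <- cohorts$participant_id[i]
    n_days <- as.integer(cohorts$enrolment_end[i] - cohorts$enrolment_start[i]) + 1L
    pd <- prompts$date[prompts$participant_id == pid]
    n_daily <- sum(study$daily$participant_id == pid)
    n_matched <- match_weekly_prompts(
      pd, study$weekly$date[study$weekly$participant_id == pid])
    tibble::tibble(
      participant_id = pid, cohort = cohorts$cohort[i],
      n_days = n_days, n_prompts = length(pd),
      daily_adherence = 100 * n_daily / n_days,
      weekly_adherence = if (length(pd)) 100 * n_matched / length(pd) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort adherence as a function of time into the study
#'
#' Splits each participant's enrolment into successive tumbling windows of
#' `window_days` days, computes the participant's adherence within each
#' complete window, and summarises each cohort by the median and
#' interquartile range. Participants contribute only to windows that fit
#' entirely inside their enrolment.
#'
#' @param study An `mz_study` object.
#' @param window_days Window length in days, default 30.
#' @param stream `"daily"` (Mood Zoom, same-day rule) or `"weekly"`
#'   (prompt-based, +/- 2 day rule).
#' @return Tibble: `cohort`, `window` (1-based index), `window_start_day`,
#'   `n_participants`, `median_adherence`, `iqr_adherence`.
#' @export
adherence_curve <- function(study, window_days = 30,
                            stream = c("daily", "weekly")) {
  stream <- match.arg(stream)
  stopifnot(inherits(study, "mz_study"))
  cohorts <- study$cohorts
  prompts <- study$prompts
  if (is.null(prompts)) prompts <- infer_prompts(study$weekly, cohorts)
  rows <- list()
  for (i in seq_len(nrow(cohorts))) {
    pid <- cohorts$participant_id[i]
    start <- cohorts$enrolment_start[i]
    n_days <- as.integer(cohorts$enrolment_end[i] - start) + 1L
    n_windows <- n_days %/% window_days
    if (n_windows == 0) next
    for (w in seq_len(n_windows)) {
      w_start <- start + (w - 1) * window_days
      w_end <- w_start + window_days - 1
      adh <- if (stream == "daily") {
        d <- study$daily$date[study$daily$participant_id == pid]
        100 * sum(d >= w_start & d <= w_end) / window_days
      } else {
        pd <- prompts$date[prompts$participant_id == pid]
        pd <- pd[pd >= w_start & pd <= w_end]
        if (length(pd) == 0) next
        rec <- study$weekly$date[study$weekly$participant_id == pid]
        100 * match_weekly_prompts(pd, rec) / length(pd)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        cohort = cohorts$cohort[i], participant_id = pid,
        window = w, adherence = adh)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$cohort, .data$window) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      median_adherence = stats::median(.data$adherence),
      iqr_adherence = stats::IQR(.data$adherence),
      .groups = "drop") |>
    dplyr::mutate(window_start_day = (.data$window - 1) * window_days + 1,
                  .after = "window")
}

#' Weekly instrument totals
#'
#' Scores every weekly record: ASRM total (item sum), QIDS total (sum of
#' the nine domain scores), GAD-7 total (item sum), and passes the EQ-5D
#' VAS through. Also returns the nine QIDS domain scores as
#' `qids_<domain>` columns.
#'
#' @param study An `mz_study` object (or a weekly-format tibble).
#' @return Tibble with `participant_id`, `date`, domain columns and
#'   `asrm_total`, `qids_total`, `gad7_total`, `eq5d_vas`.
#' @export
weekly_totals <- function(study) {
  weekly <- if (inherits(study, "mz_study")) study$weekly else study
  if (nrow(weekly) == 0) {
    out <- empty_weekly()[c("participant_id", "date", "eq5d_vas")]
    for (d in qids_domain_names()) out[[paste0("qids_", d)]] <- integer(0)
    out$asrm_total <- integer(0); out$qids_total <- integer(0)
    out$gad7_total <- integer(0)
    return(out)
  }
  out <- weekly[c("participant_id", "date")]
  for (d in names(qids_domain_map)) {
    block <- as.matrix(weekly[paste0("qids_", qids_domain_map[[d]])])
    out[[paste0("qids_", d)]] <- as.integer(apply(block, 1, max))
  }
  out$asrm_total <- as.integer(rowSums(weekly[paste0("asrm_", 1:5)]))
  out$qids_total <- as.integer(rowSums(out[paste0("qids_", names(qids_domain_map))]))
  out$gad7_total <- as.integer(rowSums(weekly[paste0("gad7_", 1:7)]))
  out$eq5d_vas <- weekly$eq5d_vas
  out
}

#' Align daily Mood Zoom records to weekly instrument records
#'
#' For each weekly record dated t, summarises the participant's available
#' daily records by one of four rules: `mean_prev_week` / `median_prev_week`
#' use the seven calendar days strictly preceding t (\[t-7, t-1\]);
#' `last3_days` uses \[t-3, t-1\]; `same_day` uses the record at t itself.
#' Missing days inside a window are simply absent from the summary; weekly
#' records with no qualifying daily record are dropped and counted in the
#' `dropped` attribute.
#'
#' @param study An `mz_study` object.
#' @param method One of `"mean_prev_week"`, `"median_prev_week"`,
#'   `"last3_days"`, `"same_day"`.
#' @param include_rating_day For the two week-window methods, also include
#'   the rating day t itself (default FALSE).
#' @return Tibble with one row per emitted pair: `participant_id`,
#'   `cohort`, `date` (weekly record date), `n_days_used`, the six
#'   summarised Mood Zoom items, the QIDS domain columns and instrument
#'   totals from [weekly_totals()]. Attribute `dropped` counts weekly
#'   records with no qualifying daily data.
#' @export
align_daily_to_weekly <- function(study,
                                  method = c("mean_prev_week",
                                             "median_prev_week",
                                             "last3_days", "same_day"),
                                  include_rating_day = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(study, "mz_study"))
  totals <- weekly_totals(study)
  daily_by_pid <- split(study$daily, study$daily$participant_id)
  summarise_fun <- if (method == "median_prev_week") stats::median else mean
  rows <- vector("list", nrow(totals))
  dropped <- 0L
  for (i in seq_len(nrow(totals))) {
    pid <- totals$participant_id[i]
    daily <- daily_by_pid[[pid]]
    if (is.null(daily)) { dropped <- dropped + 1L; next }
    t <- totals$date[i]
    lo <- switch(method,
                 mean_prev_week = t - 7, median_prev_week = t - 7,
                 last3_days = t - 3, same_day = t)
    hi <- if (method == "same_day") t else t - 1
    if (include_rating_day && method %in% c("mean_prev_week", "median_prev_week")) {
      hi <- t
    }
    sel <- daily$date >= lo & daily$date <= hi
    n_used <- sum(sel)
    if (n_used == 0) { dropped <- dropped + 1L; next }
    summ <- vapply(mz_items(), function(it) summarise_fun(daily[[it]][sel]),
                   numeric(1))
    rows[[i]] <- dplyr::bind_cols(
      totals[i, ], tibble::as_tibble(as.list(summ)),
      tibble::tibble(n_days_used = n_used))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::left_join(out, study$cohorts[c("participant_id", "cohort")],
                            by = "participant_id") |>
      dplyr::relocate("cohort", .after = "participant_id")
  }
  attr(out, "dropped") <- dropped
  attr(out, "method") <- method
  out
}
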