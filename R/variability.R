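#' Time-series variability statistics
#'
#' Four scalar summaries of within-person variability applied throughout the
#' package: the sample standard deviation, the mean Teager-Kaiser energy
#' operator (TKEO), the Shannon entropy of the empirical value distribution,
#' and the root mean squared successive differences (RMSSD). TKEO is
#' sensitive to both the amplitude and the frequency of fluctuations; RMSSD
#' to amplitude changes between consecutive observations; entropy to the
#' spread of the value distribution irrespective of ordering.
#'
#' @name variability-statistics
NULL

check_series <- function(x, min_n, what) {
  if (anyNA(x)) stop(what, ": series contains missing values", call. = FALSE)
  if (length(x) < min_n) {
    stop(sprintf("%s requires at least %d observations, got %d",
                 what, min_n, length(x)), call. = FALSE)
  }
  invisible(x)
}

# Split positions 1..N into runs of consecutive observations when dates and
# a maximum tolerated gap are supplied; otherwise one run.
series_segments <- function(n, dates = NULL, max_gap = NULL) {
  if (is.null(dates) || is.null(max_gap) || n < 2) return(list(seq_len(n)))
  gaps <- diff(as.numeric(dates))
  if (any(gaps <= 0)) stop("dates must be strictly increasing", call. = FALSE)
  brk <- which(gaps > max_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  Map(seq.int, starts, ends)
}

#' @rdname variability-statistics
#' @param x Numeric series in observation order.
#' @return `series_std()`: sample standard deviation (denominator N-1).
#' @export
series_std <- function(x) {
  check_series(x, 2, "series_std")
  stats::sd(x)
}

#' @rdname variability-statistics
#' @param dates Optional vector of observation dates (strictly increasing),
#'   used only when `max_gap` is given.
#' @param max_gap Optional maximum calendar gap (days) between observations
#'   treated as adjacent; wider gaps split the series and interior terms are
#'   pooled across segments. Default `NULL`: observed records are treated as
#'   adjacent regardless of gaps.
#' @param variant `"standard"` computes the Teager-Kaiser interior term
#'   x_i^2 - x_(i-1) x_(i+1); `"printed"` computes x_i^2 - x_(i+1)^2, a
#'   telescoping variant retained for audit only.
#' @return `series_tkeo()`: mean of the interior Teager-Kaiser terms with a
#'   1/N normalizer (N = series length); may be negative.
#' @export
series_tkeo <- function(x, dates = NULL, max_gap = NULL,
                        variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  check_series(x, 3, "series_tkeo")
  n <- length(x)
  segs <- series_segments(n, dates, max_gap)
  total <- 0
  for (ix in segs) {
    s <- x[ix]
    m <- length(s)
    if (m < 3) next
    i <- 2:(m - 1)
    total <- total + sum(
      if (variant == "standard") s[i]^2 - s[i - 1] * s[i + 1]
      else                       s[i]^2 - s[i + 1]^2
    )
  }
  total / n
}

#' @rdname variability-statistics
#' @param base Logarithm base for the entropy; default natural log.
#' @return `series_entropy()`: Shannon entropy of the empirical distribution
#'   of distinct observed values; 0 for a constant series, at most
#'   log(number of distinct values).
#' @export
series_entropy <- function(x, base = exp(1)) {
  check_series(x, 1, "series_entropy")
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p, base = base))
}

#' @rdname variability-statistics
#' @return `series_rmssd()`: square root of the mean (1/N normalizer, N-1
#'   terms) of squared successive differences.
#' @export
series_rmssd <- function(x, dates = NULL, max_gap = NULL) {
  check_series(x, 2, "series_rmssd")
  n <- length(x)
  segs <- series_segments(n, dates, max_gap)
  total <- 0
  for (ix in segs) {
    s <- x[ix]
    if (length(s) < 2) next
    total <- total + sum(diff(s)^2)
  }
  sqrt(total / n)
}

# All four statistics for one series; cells that cannot be computed are NA
# with the reason recorded.
variability_cells <- function(x, dates = NULL, max_gap = NULL,
                              entropy_base = exp(1),
                              tkeo_variant = "standard") {
  n <- length(x)
  reason <- if (n < 2) sprintf("series too short (n=%d)", n) else NA_character_
  tibble::tibble(
    n = n,
    std     = if (n >= 2) series_std(x) else NA_real_,
    tkeo    = if (n >= 3) series_tkeo(x, dates, max_gap, tkeo_variant) else NA_real_,
    entropy = if (n >= 1) series_entropy(x, entropy_base) else NA_real_,
    rmssd   = if (n >= 2) series_rmssd(x, dates, max_gap) else NA_real_,
    reason  = if (n < 3) sprintf("series too short (n=%d)", n) else NA_character_
  )
}

#' Per-participant variability profile
#'
#' Computes all four variability statistics for each participant on the
#' weekly instrument totals (ASRM, QIDS, GAD-7, EQ-5D VAS) and the daily
#' Mood Zoom factor series (MZneg, MZpos, MZirr). Series are taken in date
#' order; statistics that need more observations than a series has are
#' returned as `NA` with the reason in the `reason` column.
#'
#' @param study An `mz_study` object.
#' @param loadings Fitted [fit_mz_pca()] loadings used for the factor series.
#' @param max_gap Optional maximum calendar gap in days treated as adjacent
#'   for TKEO/RMSSD (see [series_tkeo()]).
#' @param entropy_base Logarithm base for the entropy.
#' @param tkeo_variant TKEO variant, `"standard"` or `"printed"`.
#' @return Tibble with columns `participant_id`, `cohort`, `series`, `n`,
#'   `std`, `tkeo`, `entropy`, `rmssd`, `reason`; one row per participant
#'   and series.
#' @export
variability_profile <- function(study, loadings, max_gap = NULL,
                                entropy_base = exp(1),
                                tkeo_variant = "standard") {
  stopifnot(inherits(study, "mz_study"))
  weekly <- weekly_totals(study)
  fs <- factor_scores(study$daily, loadings)
  daily <- dplyr::bind_cols(study$daily[c("participant_id", "date")], fs)

  one <- function(df, col) {
    df <- df[order(df$date), ]
    variability_cells(df[[col]], dates = df$date, max_gap = max_gap,
                      entropy_base = entropy_base, tkeo_variant = tkeo_variant)
  }
  series_defs <- list(
    ASRM  = list(weekly, "asrm_total"),
    QIDS  = list(weekly, "qids_total"),
    `GAD-7` = list(weekly, "gad7_total"),
    `EQ-5D` = list(weekly, "eq5d_vas"),
    MZneg = list(daily, "MZneg"),
    MZpos = list(daily, "MZpos"),
    MZirr = list(daily, "MZirr")
  )
  out <- lapply(names(series_defs), function(nm) {
    src <- series_defs[[nm]][[1]]
    col <- series_defs[[nm]][[2]]
    src |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::group_modify(~ one(.x, col)) |>
      dplyr::ungroup() |>
      dplyr::mutate(series = nm, .after = "participant_id")
  })
  dplyr::bind_rows(out) |>
    dplyr::left_join(study$cohorts[c("participant_id", "cohort")],
                     by = "participant_id") |>
    dplyr::relocate("cohort", .after = "participant_id")
}
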