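# All permutations of 1..n as an n! x n matrix (n <= 9).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- matrix(0L, rows, n)
    block[, 1] <- k
    block[, -1] <- ifelse(sub >= k, sub + 1L, sub)
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Spearman rank correlation with a two-regime p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' For n <= 9 the p-value is exact, from full enumeration of the n!
#' permutations of one rank vector; for larger n it uses the large-sample
#' t approximation t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors without missing values, length >= 3.
#' @return List with `rho`, `p`, `n`, `method` and `defined` (FALSE when
#'   either input has zero variance, in which case `rho` and `p` are `NA`).
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: drop incomplete pairs first",
                                 call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined", defined = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    # |rho| is a monotone function of |centered cross-product| for fixed
    # rank marginals, so enumerate the cross-product instead of rho
    perms <- all_perms(n)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    cp_obs <- sum((rx - mean(rx)) * ry)
    cp_perm <- as.numeric(ry_perm %*% cbind(rx - mean(rx)))
    p <- mean(abs(cp_perm) >= abs(cp_obs) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method, defined = TRUE)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided test of the null that the two samples come from distributions
#' with equal medians. The exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 20
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )$p.value
}

association_row_defs <- function() {
  list(
    asrm = stats::setNames(paste0("asrm_", 1:5), paste0("asrm_", asrm_items())),
    qids = stats::setNames(paste0("qids_", qids_domain_names()),
                           paste0("qids_", qids_domain_names())),
    gad7 = stats::setNames(paste0("gad7_", 1:7), paste0("gad7_", gad7_items())),
    eq5d = c(eq5d_vas = "eq5d_vas"),
    totals = c(total_asrm = "asrm_total", total_qids = "qids_total",
               total_gad7 = "gad7_total")
  )
}

#' Association matrix between weekly instruments and Mood Zoom
#'
#' Aligns the daily Mood Zoom records to the weekly records (see
#' [align_daily_to_weekly()]), pools the aligned pairs across all
#' participants, and computes a Spearman correlation for every
#' (weekly variable, Mood Zoom variable) cell. Weekly variables are the
#' five ASRM items, nine QIDS domains, seven GAD-7 items, the EQ-5D VAS
#' and the three instrument totals; Mood Zoom variables are the six
#' summarised items and the three factor scores. Cells are flagged
#' *strong* when |rho| >= 0.3 and *significant* when p < 1e-4.
#'
#' @param study An `mz_study` object.
#' @param loadings Fitted [fit_mz_pca()] loadings for the factor columns.
#' @param method Alignment method, see [align_daily_to_weekly()].
#' @param strong_threshold Absolute-rho threshold for the strong flag,
#'   default 0.3.
#' @param alpha Significance threshold on the p-value, default 1e-4.
#' @return Tibble with one row per cell: `weekly_var`, `mz_var`, `rho`,
#'   `p`, `n`, `strong`, `significant` (`NA` flags for cells with fewer
#'   than 3 pooled pairs or undefined correlation).
#' @export
association_table <- function(study, loadings, method = "mean_prev_week",
                              strong_threshold = 0.3, alpha = 1e-4) {
  aligned <- align_daily_to_weekly(study, method = method)
  if (nrow(aligned) == 0) stop("no aligned pairs available", call. = FALSE)
  fs <- factor_scores(aligned, loadings)
  aligned <- dplyr::bind_cols(aligned, fs)
  weekly_vars <- unlist(unname(association_row_defs()))
  mz_vars <- stats::setNames(c(mz_items(), c("MZneg", "MZpos", "MZirr")),
                             c(mz_items(), c("MZneg", "MZpos", "MZirr")))
  rows <- list()
  for (wi in seq_along(weekly_vars)) {
    for (mi in seq_along(mz_vars)) {
      x <- aligned[[weekly_vars[wi]]]
      y <- aligned[[mz_vars[mi]]]
      cell <- if (length(x) >= 3) {
        spearman_assoc(x, y)
      } else {
        list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        weekly_var = names(weekly_vars)[wi],
        mz_var = names(mz_vars)[mi],
        rho = cell$rho, p = cell$p, n = cell$n,
        strong = if (is.na(cell$rho)) NA else abs(cell$rho) >= strong_threshold,
        significant = if (is.na(cell$p)) NA else cell$p < alpha
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_tests") <- sum(!is.na(out$p))
  attr(out, "method") <- method
  attr(out, "dropped") <- attr(aligned, "dropped")
  out
}

#' Per-participant median scores for the headline summary
#'
#' For each participant: the median of the weekly ASRM, QIDS and GAD-7
#' totals and the EQ-5D VAS, and the median of the daily MZneg, MZpos and
#' MZirr factor series. These per-participant medians are the inputs of the
#' cohort comparison.
#'
#' @param study An `mz_study` object.
#' @param loadings Fitted [fit_mz_pca()] loadings.
#' @return Long tibble: `participant_id`, `cohort`, `variable`, `value`.
#' @export
summarise_scores <- function(study, loadings) {
  stopifnot(inherits(study, "mz_study"))
  totals <- weekly_totals(study)
  weekly_long <- totals |>
    dplyr::select("participant_id", ASRM = "asrm_total", QIDS = "qids_total",
                  `GAD-7` = "gad7_total", `EQ-5D` = "eq5d_vas") |>
    tidyr::pivot_longer(-"participant_id", names_to = "variable")
  fs <- factor_scores(study$daily, loadings)
  daily_long <- dplyr::bind_cols(study$daily["participant_id"], fs) |>
    tidyr::pivot_longer(-"participant_id", names_to = "variable")
  dplyr::bind_rows(weekly_long, daily_long) |>
    dplyr::group_by(.data$participant_id, .data$variable) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop") |>
    dplyr::left_join(study$cohorts[c("participant_id", "cohort")],
                     by = "participant_id") |>
    dplyr::relocate("cohort", .after = "participant_id")
}

#' Cohort comparison table (median +/- iqr and pairwise Wilcoxon tests)
#'
#' Summarises per-participant values by cohort median and interquartile
#' range (type-7 quantiles) and tests every cohort pair with the two-sided
#' Wilcoxon rank-sum test. No multiple-testing correction is applied; the
#' number of tests is reported in the `n_tests` attribute so users can
#' apply their own.
#'
#' @param values Long tibble with columns `participant_id`, `cohort`,
#'   `variable`, `value` (e.g. from [summarise_scores()] or a pivoted
#'   [variability_profile()]).
#' @param alpha Significance marking threshold, default 0.05.
#' @return Tibble with one row per variable: `median_<cohort>` and
#'   `iqr_<cohort>` columns for every cohort, then `p_<a>_vs_<b>` and
#'   `sig_<a>_vs_<b>` columns for every cohort pair. Cohorts with no
#'   usable participants for a variable yield `NA` cells.
#' @export
comparison_table <- function(values, alpha = 0.05) {
  stopifnot(all(c("participant_id", "cohort", "variable", "value") %in%
                  names(values)))
  cohorts <- unique(values$cohort)
  pairs <- if (length(cohorts) >= 2) utils::combn(cohorts, 2, simplify = FALSE)
           else list()
  vars <- unique(values$variable)
  rows <- lapply(vars, function(v) {
    row <- tibble::tibble(variable = v)
    sub <- values[values$variable == v & !is.na(values$value), ]
    for (coh in cohorts) {
      x <- sub$value[sub$cohort == coh]
      row[[paste0("median_", coh)]] <- if (length(x)) stats::median(x) else NA_real_
      row[[paste0("iqr_", coh)]] <- if (length(x)) stats::IQR(x, type = 7) else NA_real_
    }
    for (pr in pairs) {
      a <- sub$value[sub$cohort == pr[1]]
      b <- sub$value[sub$cohort == pr[2]]
      nm <- paste0(pr[1], "_vs_", pr[2])
      p <- if (length(a) && length(b)) wilcoxon_rank_sum(a, b) else NA_real_
      row[[paste0("p_", nm)]] <- p
      row[[paste0("sig_", nm)]] <- if (is.na(p)) NA else p < alpha
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_tests") <- sum(!is.na(as.matrix(
    out[grep("^p_", names(out))])))
  attr(out, "alpha") <- alpha
  out
}

#' Variability profile in long comparison format
#'
#' Pivots a [variability_profile()] into the `(participant, cohort,
#' variable, value)` layout consumed by [comparison_table()], naming
#' variables `<series>_<statistic>` (e.g. `MZneg_rmssd`).
#'
#' @param profile Output of [variability_profile()].
#' @return Long tibble with columns `participant_id`, `cohort`,
#'   `variable`, `value`.
#' @export
variability_long <- function(profile) {
  profile |>
    dplyr::select("participant_id", "cohort", "series",
                  "std", "tkeo", "entropy", "rmssd") |>
    tidyr::pivot_longer(c("std", "tkeo", "entropy", "rmssd"),
                        names_to = "stat") |>
    dplyr::mutate(variable = paste0(.data$series, "_", .data$stat)) |>
    dplyr::select("participant_id", "cohort", "variable", "value")
}
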