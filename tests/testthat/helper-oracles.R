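# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package).

oracle_std <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (x[i] - m)^2
  sqrt(acc / (n - 1))
}

oracle_tkeo <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in 2:(n - 1)) acc <- acc + x[i]^2 - x[i - 1] * x[i + 1]
  acc / n
}

oracle_entropy <- function(x, base = exp(1)) {
  n <- length(x)
  acc <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / n
    acc <- acc - p * log(p, base = base)
  }
  acc
}

oracle_rmssd <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n - 1)) acc <- acc + (x[i + 1] - x[i])^2
  sqrt(acc / n)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) group assignments (tie-free data). Mirrors the standard
# two-sided rule: double the smaller tail of the rank-sum statistic.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)])
  sets <- utils::combn(length(pooled), m)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Exact two-sided Spearman p by enumerating permutations of y.
oracle_spearman_p <- function(x, y) {
  rho_obs <- cor(rank(x), rank(y))
  perms <- combinat_perms(length(y))
  rho_all <- apply(perms, 1, function(ix) cor(rank(x), rank(y[ix])))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# Small three-cohort study for fast structural tests.
tiny_config <- function(seed = 42, n_participants = 3, n_days = 60,
                        daily_missing_prob = 0.1,
                        weekly_missing_prob = 0.1) {
  study_config(
    cohorts = list(
      cohort_params("HC", n_participants, n_days,
                    neg_mean = 2.0, pos_mean = 4.2,
                    neg_sd = 0.5, pos_sd = 0.6,
                    irritability_share = 0.9, irr_sd = 0.3,
                    daily_missing_prob = daily_missing_prob,
                    weekly_missing_prob = weekly_missing_prob),
      cohort_params("BD", n_participants, n_days,
                    neg_mean = 3.2, pos_mean = 3.9,
                    neg_sd = 0.9, pos_sd = 0.8,
                    irritability_share = 0.75, irr_sd = 0.55,
                    daily_missing_prob = daily_missing_prob,
                    weekly_missing_prob = weekly_missing_prob),
      cohort_params("BPD", n_participants, n_days,
                    neg_mean = 4.2, pos_mean = 4.4,
                    neg_sd = 1.3, pos_sd = 1.0,
                    irritability_share = 0.6, irr_sd = 0.85,
                    daily_missing_prob = daily_missing_prob,
                    weekly_missing_prob = weekly_missing_prob)
    ),
    seed = seed
  )
}

tiny_study <- function(...) generate_study(tiny_config(...))

# Hand-built two-participant study with fully known records.
manual_study <- function(daily_dates, daily_items = NULL,
                         weekly_dates = as.Date(character(0)),
                         start = as.Date("2021-03-01"), n_days = 30,
                         pid = "P1") {
  nd <- length(daily_dates)
  if (is.null(daily_items)) {
    daily_items <- matrix(4L, nd, 6)
  }
  colnames(daily_items) <- mz_items()
  daily <- dplyr::bind_cols(
    tibble::tibble(participant_id = rep(pid, nd), date = daily_dates),
    tibble::as_tibble(daily_items))
  nw <- length(weekly_dates)
  weekly <- tibble::as_tibble(c(
    list(participant_id = rep(pid, nw), date = weekly_dates),
    stats::setNames(rep(list(rep(1L, nw)), 5), paste0("asrm_", 1:5)),
    stats::setNames(rep(list(rep(1L, nw)), 16), paste0("qids_", 1:16)),
    stats::setNames(rep(list(rep(1L, nw)), 7), paste0("gad7_", 1:7)),
    list(eq5d_vas = rep(70, nw))))
  cohorts <- tibble::tibble(participant_id = pid, cohort = "HC",
                            enrolment_start = start,
                            enrolment_end = start + n_days - 1)
  mz_study(daily, weekly, cohorts)
}
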