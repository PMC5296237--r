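#' Cohort-level generator parameters
#'
#' Parameters of the synthetic longitudinal cohort generator. Each cohort is
#' driven by two latent daily AR(1) affect processes (negative and positive),
#' expressed directly on the 1--7 Mood Zoom item scale: anxious and sad load
#' on negative affect, elated and energetic on positive affect, and angry
#' and irritable on negative affect scaled by `irritability_share`.
#'
#' @param label Cohort label (e.g. "HC", "BD", "BPD").
#' @param n_participants Number of participants (0 allowed; an empty cohort
#'   is generated with a warning).
#' @param n_days Follow-up length in days (>= 14).
#' @param neg_mean,pos_mean Latent affect means on the 1--7 item scale.
#' @param neg_sd,pos_sd AR(1) innovation standard deviations (> 0).
#' @param ar_coef AR(1) autocorrelation in \[0, 1).
#' @param daily_missing_prob,weekly_missing_prob Independent per-prompt
#'   missingness probabilities in \[0, 1).
#' @param irritability_share Multiplier routing negative affect to the angry
#'   and irritable items (> 0; values below 1 damp the irritability channel
#'   relative to anxiety/sadness).
#' @param irr_sd Innovation standard deviation of the irritability-specific
#'   AR(1) latent added to the angry and irritable items; without it the
#'   negative items would carry a rank-one signal and the third principal
#'   component would be pure item noise. Default `0.6 * neg_sd`.
#' @param item_noise_sd Standard deviation of the independent per-item daily
#'   noise added before rounding to the Likert scale.
#' @param weekly_noise_sd Standard deviation of the per-item noise on the
#'   weekly instrument item scale.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(label, n_participants, n_days,
                          neg_mean, pos_mean, neg_sd, pos_sd,
                          ar_coef = 0.5,
                          daily_missing_prob = 0.15,
                          weekly_missing_prob = 0.15,
                          irritability_share = 0.85,
                          irr_sd = NULL,
                          item_noise_sd = 0.7,
                          weekly_noise_sd = 0.4) {
  p <- list(label = as.character(label),
            n_participants = as.integer(n_participants),
            n_days = as.integer(n_days),
            neg_mean = neg_mean, pos_mean = pos_mean,
            neg_sd = neg_sd, pos_sd = pos_sd,
            ar_coef = ar_coef,
            daily_missing_prob = daily_missing_prob,
            weekly_missing_prob = weekly_missing_prob,
            irritability_share = irritability_share,
            irr_sd = if (is.null(irr_sd)) 0.6 * neg_sd else irr_sd,
            item_noise_sd = item_noise_sd,
            weekly_noise_sd = weekly_noise_sd)
  if (nchar(p$label) == 0) stop("cohort label must be non-empty", call. = FALSE)
  if (p$n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
  if (p$n_days < 14) stop("n_days must be >= 14", call. = FALSE)
  if (p$neg_sd <= 0 || p$pos_sd <= 0) stop("sds must be > 0", call. = FALSE)
  if (p$ar_coef < 0 || p$ar_coef >= 1) stop("ar_coef must be in [0,1)", call. = FALSE)
  for (f in c("daily_missing_prob", "weekly_missing_prob")) {
    if (p[[f]] < 0 || p[[f]] >= 1) stop(f, " must be in [0,1)", call. = FALSE)
  }
  if (p$irritability_share <= 0) stop("irritability_share must be > 0", call. = FALSE)
  if (p$irr_sd < 0) stop("irr_sd must be >= 0", call. = FALSE)
  structure(p, class = "cohort_params")
}

#' Study-level generator configuration
#'
#' @param cohorts List of [cohort_params()] objects with unique labels.
#' @param seed Master integer seed; a fixed configuration reproduces the
#'   generated study bit-for-bit.
#' @param weekly_prompt_weekday Weekday of the weekly prompt, 0 (Sunday) to
#'   6 (Saturday).
#' @param start_date Nominal enrolment start date shared by all
#'   participants.
#' @return A `study_config` list.
#' @export
study_config <- function(cohorts, seed = 1L, weekly_prompt_weekday = 1L,
                         start_date = as.Date("2020-01-06")) {
  stopifnot(length(cohorts) >= 1)
  if (!all(vapply(cohorts, inherits, logical(1), "cohort_params"))) {
    stop("cohorts must be a list of cohort_params objects", call. = FALSE)
  }
  labels <- vapply(cohorts, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("cohort labels must be unique", call. = FALSE)
  if (weekly_prompt_weekday < 0 || weekly_prompt_weekday > 6) {
    stop("weekly_prompt_weekday must be in 0..6", call. = FALSE)
  }
  structure(list(cohorts = stats::setNames(cohorts, labels),
                 seed = as.integer(seed),
                 weekly_prompt_weekday = as.integer(weekly_prompt_weekday),
                 start_date = as.Date(start_date)),
            class = "study_config")
}

#' Default three-cohort presets
#'
#' Presets for a healthy-control (HC), bipolar-disorder (BD) and
#' borderline-personality-disorder (BPD) cohort of 30 participants each,
#' followed for 270 days with ~85% adherence. Negative-affect level and
#' day-to-day variability are both ordered HC < BD < BPD; the
#' irritability-specific latent variance is ordered the same way while the
#' share of negative affect routed to the angry/irritable items falls
#' (HC 0.90, BD 0.75, BPD 0.60), so the variability of the third Mood Zoom
#' component grows from HC to BPD while its level falls. These orderings,
#' not any particular printed value, are the structure the generator is
#' designed to realise.
#'
#' @param n_participants Participants per cohort, default 30.
#' @param n_days Follow-up days per participant, default 270.
#' @param seed Master seed, default 1.
#' @return A [study_config()] object.
#' @export
default_study_config <- function(n_participants = 30, n_days = 270, seed = 1L) {
  study_config(
    cohorts = list(
      cohort_params("HC",  n_participants, n_days,
                    neg_mean = 2.0, pos_mean = 4.2,
                    neg_sd = 0.5, pos_sd = 0.6,
                    irritability_share = 0.90, irr_sd = 0.30),
      cohort_params("BD",  n_participants, n_days,
                    neg_mean = 3.2, pos_mean = 3.9,
                    neg_sd = 0.9, pos_sd = 0.8,
                    irritability_share = 0.75, irr_sd = 0.55),
      cohort_params("BPD", n_participants, n_days,
                    neg_mean = 4.2, pos_mean = 4.4,
                    neg_sd = 1.3, pos_sd = 1.0,
                    irritability_share = 0.60, irr_sd = 0.85)
    ),
    seed = seed
  )
}

# Stationary AR(1) series of length n with innovation sd `sd` and
# autocorrelation `phi`; zero mean.
ar1_series <- function(n, phi, sd) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, if (phi > 0) sd / sqrt(1 - phi^2) else sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, sd)
    for (t in 2:n) z[t] <- phi * z[t - 1] + e[t - 1]
  }
  z
}

# Deterministic sub-seed below 2^31 from the master seed and a string key
# (cohort label + participant index), so adding participants or cohorts
# never perturbs earlier ones.
sub_seed <- function(master, key) {
  h <- abs(as.numeric(master)) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

weekly_prompt_dates <- function(start, end, weekday) {
  offset <- (weekday - as.POSIXlt(start)$wday) %% 7
  first <- start + offset
  if (first > end) return(as.Date(character(0)))
  seq(first, end, by = 7)
}

#' Generate one synthetic participant timeline
#'
#' Draws latent daily AR(1) processes for negative affect, positive affect
#' and an irritability-specific residual, maps them to the six Mood Zoom
#' items (affine map + independent item noise + rounding + clipping to
#' 1--7; angry/irritable carry `irritability_share` times the negative
#' latent plus the irritability latent), generates weekly instrument
#' responses on prompt days from the mean latent over the preceding seven
#' days (QIDS and GAD-7 driven by negative
#' affect, ASRM by positive affect, EQ-5D VAS inversely by negative affect),
#' then drops daily and weekly records independently at the configured
#' missingness probabilities and jitters retained weekly responses by an
#' integer offset in -2..2 days (clamped to the enrolment window).
#'
#' @param params A [cohort_params()] object.
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Participant identifier string.
#' @param start_date Enrolment start date.
#' @param weekly_prompt_weekday Weekday (0--6) of the weekly prompt.
#' @return List with tibbles `daily`, `weekly`, `prompts` and the one-row
#'   `cohorts` metadata.
#' @export
generate_participant <- function(params, participant_seed, participant_id,
                                 start_date = as.Date("2020-01-06"),
                                 weekly_prompt_weekday = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(participant_seed)

  nd <- params$n_days
  dates <- start_date + 0:(nd - 1)
  end_date <- dates[nd]
  zn <- params$neg_mean + ar1_series(nd, params$ar_coef, params$neg_sd)
  zp <- params$pos_mean + ar1_series(nd, params$ar_coef, params$pos_sd)
  zi <- ar1_series(nd, params$ar_coef, params$irr_sd)

  irr <- params$irritability_share * zn + zi
  latent <- cbind(anxious = zn, elated = zp, sad = zn,
                  angry = irr, irritable = irr, energetic = zp)
  noise <- matrix(stats::rnorm(nd * 6, 0, params$item_noise_sd), nd, 6)
  items <- clip(round(latent + noise), 1, 7)
  keep_daily <- stats::runif(nd) >= params$daily_missing_prob
  daily <- tibble::tibble(participant_id = participant_id, date = dates)
  daily <- dplyr::bind_cols(daily, tibble::as_tibble(items))[keep_daily, ]

  prompts <- weekly_prompt_dates(start_date, end_date, weekly_prompt_weekday)
  np <- length(prompts)
  keep_weekly <- stats::runif(np) >= params$weekly_missing_prob
  offsets <- sample(-2:2, np, replace = TRUE)
  resp_dates <- clip(prompts + offsets, start_date, end_date)

  weekly_rows <- vector("list", np)
  for (k in seq_len(np)) {
    if (!keep_weekly[k]) next
    window <- dates >= prompts[k] - 7 & dates <= prompts[k] - 1
    negbar <- if (any(window)) mean(zn[window]) else zn[dates == prompts[k]]
    posbar <- if (any(window)) mean(zp[window]) else zp[dates == prompts[k]]
    u <- clip((negbar - 1) / 6, 0, 1)  # negative affect on [0,1]
    v <- clip((posbar - 1) / 6, 0, 1)  # positive affect on [0,1]
    nsd <- params$weekly_noise_sd
    qids <- clip(round(3.2 * u - 0.3 + stats::rnorm(16, 0, nsd)), 0, 3)
    gad7 <- clip(round(3.2 * u - 0.3 + stats::rnorm(7, 0, nsd)), 0, 3)
    asrm <- clip(round(2.5 * v - 1 + stats::rnorm(5, 0, nsd)), 0, 4)
    vas  <- clip(round(100 * (1 - u) + stats::rnorm(1, 0, 8)), 0, 100)
    row <- c(list(participant_id = participant_id, date = resp_dates[k]),
             stats::setNames(as.list(as.integer(asrm)), paste0("asrm_", 1:5)),
             stats::setNames(as.list(as.integer(qids)), paste0("qids_", 1:16)),
             stats::setNames(as.list(as.integer(gad7)), paste0("gad7_", 1:7)),
             list(eq5d_vas = as.numeric(vas)))
    weekly_rows[[k]] <- tibble::as_tibble(row)
  }
  weekly <- dplyr::bind_rows(weekly_rows)
  if (nrow(weekly) == 0) weekly <- empty_weekly()

  list(
    daily = daily,
    weekly = weekly,
    prompts = tibble::tibble(participant_id = participant_id, date = prompts),
    cohorts = tibble::tibble(participant_id = participant_id,
                             cohort = params$label,
                             enrolment_start = start_date,
                             enrolment_end = end_date)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full synthetic study
#'
#' Concatenates per-participant generations across cohorts. Each participant
#' gets a deterministic sub-seed derived from the master seed and the
#' cohort label plus participant index, so identical configurations are
#' reproduced bit-for-bit and adding participants never perturbs earlier
#' ones.
#'
#' @param config A [study_config()] object.
#' @return An [mz_study] object.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  parts <- list()
  for (params in config$cohorts) {
    if (params$n_participants == 0) {
      warning(sprintf("cohort '%s' has zero participants", params$label))
      next
    }
    for (i in seq_len(params$n_participants)) {
      pid <- sprintf("%s_%03d", params$label, i)
      seed_i <- sub_seed(config$seed, paste0(params$label, ":", i))
      parts[[pid]] <- generate_participant(
        params, seed_i, pid,
        start_date = config$start_date,
        weekly_prompt_weekday = config$weekly_prompt_weekday
      )
    }
  }
  if (length(parts) == 0) stop("no participants generated", call. = FALSE)
  mz_study(
    daily = dplyr::bind_rows(lapply(parts, `[[`, "daily")),
    weekly = dplyr::bind_rows(lapply(parts, `[[`, "weekly")),
    cohorts = dplyr::bind_rows(lapply(parts, `[[`, "cohorts")),
    prompts = dplyr::bind_rows(lapply(parts, `[[`, "prompts")),
    provenance = config
  )
}
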