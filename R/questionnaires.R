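#' @importFrom rlang .data
NULL

#' Item labels of the daily Mood Zoom questionnaire
#'
#' The six mood descriptors rated daily on a 1--7 Likert scale, in canonical
#' order: anxious, elated, sad, angry, irritable, energetic.
#'
#' @return Character vector of length 6.
#' @export
mz_items <- function() {
  c("anxious", "elated", "sad", "angry", "irritable", "energetic")
}

#' ASRM item labels
#' @return Character vector of length 5.
#' @export
asrm_items <- function() {
  c("happy", "confident", "sleep", "talkative", "active")
}

#' GAD-7 item labels
#' @return Character vector of length 7.
#' @export
gad7_items <- function() {
  c("nervous_anxious", "control_worries", "worried", "relaxed",
    "restless", "irritable", "afraid")
}

#' QIDS-SR16 symptom-domain labels
#' @return Character vector of length 9.
#' @export
qids_domain_names <- function() {
  c("sleep", "sad", "appetite_weight", "concentration", "self_view",
    "suicide", "interest", "energy", "restless")
}

# Shared item validator: integer items in [lo, hi], length n; errors name
# the offending item index (and label when available).
check_items <- function(items, n, lo, hi, instrument, labels = NULL) {
  if (length(items) != n) {
    stop(sprintf("%s response must have exactly %d items, got %d",
                 instrument, n, length(items)), call. = FALSE)
  }
  if (anyNA(items) || !is.numeric(items)) {
    stop(sprintf("%s response contains missing or non-numeric items",
                 instrument), call. = FALSE)
  }
  bad <- which(items != round(items) | items < lo | items > hi)
  if (length(bad)) {
    lab <- if (!is.null(labels)) sprintf(" ('%s')", labels[bad[1]]) else ""
    stop(sprintf("%s item %d%s = %s is outside the allowed range %d-%d",
                 instrument, bad[1], lab, format(items[bad[1]]), lo, hi),
         call. = FALSE)
  }
  invisible(as.integer(items))
}

check_total <- function(total, lo, hi, instrument) {
  if (length(total) != 1 || is.na(total) || total < lo || total > hi) {
    stop(sprintf("%s total must be a single value in %d-%d", instrument, lo, hi),
         call. = FALSE)
  }
  invisible(total)
}

#' Score the Altman Self-Rating Mania scale
#'
#' Five items, each rated 0 (symptom-free) to 4; the total is the item sum
#' and ranges 0--20.
#'
#' @param items Numeric vector of 5 integers in 0--4 (happy, confident,
#'   sleep, talkative, active).
#' @return Integer total in 0--20.
#' @export
#' @examples
#' score_asrm(c(1, 2, 0, 3, 4))
score_asrm <- function(items) {
  check_items(items, 5, 0, 4, "ASRM", asrm_items())
  as.integer(sum(items))
}

#' Flag a possible manic episode from an ASRM total
#'
#' Applies the conventional 5.5 cut-off: integer totals of 6 or more are
#' flagged.
#'
#' @param total ASRM total score, 0--20.
#' @return Logical flag.
#' @export
classify_asrm <- function(total) {
  check_total(total, 0, 20, "ASRM")
  total > 5.5
}

# item -> domain map for standard QIDS-SR16 scoring
qids_domain_map <- list(
  sleep           = 1:4,    # initial/middle/early-morning insomnia, hypersomnia
  sad             = 5,
  appetite_weight = 6:9,    # appetite decrease/increase, weight loss/gain
  concentration   = 10,
  self_view       = 11,
  suicide         = 12,
  interest        = 13,
  energy          = 14,
  restless        = 15:16   # psychomotor slowing / agitation
)

#' Collapse the 16 QIDS-SR16 items into the nine symptom domains
#'
#' Standard QIDS-SR16 scoring: the four sleep items, the four
#' appetite/weight items and the two psychomotor items each contribute the
#' maximum of their block; the remaining six domains are single items.
#'
#' @param items Numeric vector of 16 integers in 0--3, in standard
#'   QIDS-SR16 order.
#' @return Named integer vector of 9 domain scores, each 0--3.
#' @export
#' @examples
#' qids_domains(rep(3, 16))
qids_domains <- function(items) {
  check_items(items, 16, 0, 3, "QIDS")
  out <- vapply(qids_domain_map, function(ix) max(items[ix]), numeric(1))
  stats::setNames(as.integer(out), names(qids_domain_map))
}

#' Score the QIDS-SR16
#'
#' Total = sum of the nine domain scores (each 0--3), ranging 0--27.
#'
#' @inheritParams qids_domains
#' @return Integer total in 0--27.
#' @export
score_qids <- function(items) {
  as.integer(sum(qids_domains(items)))
}

qids_band_table <- tibble::tibble(
  instrument = "QIDS",
  band  = c("normal", "mild", "moderate", "severe", "very severe"),
  lower = c(0L, 6L, 11L, 16L, 21L),
  upper = c(5L, 10L, 15L, 20L, 27L)
)

gad7_band_table <- tibble::tibble(
  instrument = "GAD-7",
  band  = c("none", "mild", "moderate", "severe"),
  lower = c(0L, 5L, 10L, 15L),
  upper = c(4L, 9L, 14L, 21L)
)

band_lookup <- function(total, table, lo, hi, instrument) {
  check_total(total, lo, hi, instrument)
  table[total >= table$lower & total <= table$upper, , drop = FALSE]
}

#' Clinical depression band of a QIDS total
#'
#' Bands: 0--5 normal, 6--10 mild, 11--15 moderate, 16--20 severe,
#' 21--27 very severe.
#'
#' @param total QIDS total score, 0--27.
#' @return One-row tibble with columns `instrument`, `band`, `lower`, `upper`.
#' @export
classify_qids <- function(total) {
  band_lookup(total, qids_band_table, 0, 27, "QIDS")
}

#' Score the GAD-7
#'
#' Seven items rated 0--3; total ranges 0--21.
#'
#' @param items Numeric vector of 7 integers in 0--3.
#' @return Integer total in 0--21.
#' @export
score_gad7 <- function(items) {
  check_items(items, 7, 0, 3, "GAD-7", gad7_items())
  as.integer(sum(items))
}

#' Clinical anxiety band of a GAD-7 total
#'
#' Cut-offs at 5, 10 and 15 for mild, moderate and severe anxiety; the
#' implied band upper edges are 4, 9 and 14.
#'
#' @param total GAD-7 total score, 0--21.
#' @return One-row tibble with columns `instrument`, `band`, `lower`, `upper`.
#' @export
classify_gad7 <- function(total) {
  band_lookup(total, gad7_band_table, 0, 21, "GAD-7")
}

#' Validate an EQ-5D visual-analogue quality-of-life rating
#'
#' Only the 0--100 VAS item is modelled; the five descriptive EQ-5D
#' dimensions are not represented.
#'
#' @param vas Numeric value in 0--100.
#' @return The validated value, invisibly classed as numeric.
#' @export
validate_eq5d <- function(vas) {
  if (length(vas) != 1 || is.na(vas) || vas < 0 || vas > 100) {
    stop("EQ-5D VAS must be a single value in 0-100", call. = FALSE)
  }
  as.numeric(vas)
}

#' Validate a daily Mood Zoom response
#'
#' Accepts exactly six integer items each in 1--7, in the order given by
#' [mz_items()].
#'
#' @param items Numeric vector of 6 integers in 1--7.
#' @return Named integer vector (anxious, elated, sad, angry, irritable,
#'   energetic).
#' @export
#' @examples
#' validate_mz(c(4, 2, 3, 1, 2, 5))
validate_mz <- function(items) {
  check_items(items, 6, 1, 7, "Mood Zoom", mz_items())
  stats::setNames(as.integer(items), mz_items())
}
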