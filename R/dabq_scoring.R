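#' Score questionnaire sleep duration
#'
#' Sleep is derived from self-reported time in bed (bed time to rise time,
#' with overnight wrap) minus sleep latency and wake after sleep onset
#' (WASO), plus the daily average of reported daytime napping over the
#' seven-day recall period.
#'
#' @param responses data.frame of questionnaire responses; see
#'   [dabq_response_columns()] for the column dictionary.
#' @return numeric vector of sleep minutes per day; `NA` where latency plus
#'   WASO meet or exceed time in bed (the record cannot be scored).
#' @export
score_sleep <- function(responses) {
  r <- responses
  tib <- clock_span_sleep(parse_hhmm(r$bed_time), parse_hhmm(r$rise_time))
  nap_daily <- r$nap_days * r$nap_duration / 7
  bad <- (r$sleep_latency + r$waso) >= tib
  out <- tib - r$sleep_latency - r$waso + nap_daily
  out[bad] <- NA_real_
  out
}

#' Score questionnaire sedentary behaviour
#'
#' SB is the sum of occupational, commuting and other non-occupational
#' sitting. Occupational sitting is the workplace span multiplied by the
#' visual-analogue proportion of that span spent sitting, averaged over the
#' week via `workdays / 7`. Commuting and "other" items are taken as
#' already-daily averages (a convention; the instrument's processing sheet is
#' external to this package).
#'
#' @inheritParams score_sleep
#' @return numeric vector of SB minutes per day.
#' @export
score_sb <- function(responses) {
  r <- responses
  span <- clock_span_work(parse_hhmm(r$work_arrival), parse_hhmm(r$work_departure))
  occ <- span * r$occupational_sb_vas * r$workdays / 7
  commute <- r$commute_duration * r$commute_sb_vas
  occ + commute + r$other_sb_duration
}

#' Score questionnaire moderate-to-vigorous physical activity
#'
#' MVPA is the sum of occupational, commuting and other non-occupational
#' contributions. Occupational and "other" MVPA are reported as days times
#' duration and averaged over 7 days; commuting MVPA is a daily duration.
#' A "no" on the occupational gate question zeroes that domain regardless of
#' any days/duration entries.
#'
#' @inheritParams score_sleep
#' @return numeric vector of MVPA minutes per day.
#' @export
score_mvpa <- function(responses) {
  r <- responses
  gate <- tolower(as.character(r$occupational_mvpa_flag)) %in% c("yes", "y", "true", "1")
  occ <- ifelse(gate, r$occupational_mvpa_days * r$occupational_mvpa_duration / 7, 0)
  other <- r$other_mvpa_days * r$other_mvpa_duration / 7
  occ + r$commute_mvpa_duration + other
}

#' Score questionnaire responses into closed 24-h compositions
#'
#' LPA is whatever remains of the 24-h day after sleep, SB and MVPA: records
#' whose remainder is negative (over-reporting) are returned with
#' `valid = FALSE` rather than truncated, so reliability and validity
#' analyses can exclude them explicitly.
#'
#' @inheritParams score_sleep
#' @return data.frame with columns `participant_id`, `occasion`, `sleep`,
#'   `sb`, `lpa`, `mvpa`, `valid`.
#' @export
score_dabq <- function(responses) {
  check_dabq_responses(responses)
  sleep <- score_sleep(responses)
  sb <- score_sb(responses)
  mvpa <- score_mvpa(responses)
  lpa <- 1440 - sleep - sb - mvpa
  valid <- !is.na(sleep) & !is.na(lpa) & lpa >= 0 & sleep >= 0 & sb >= 0 & mvpa >= 0
  out <- data.frame(
    participant_id = as.character(responses$participant_id),
    occasion = responses$occasion,
    sleep = sleep, sb = sb, lpa = lpa, mvpa = mvpa,
    valid = valid,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Column dictionary for questionnaire response tables
#'
#' @return character vector of required column names for [score_dabq()].
#' @export
dabq_response_columns <- function() {
  c(
    "participant_id", "occasion",
    "bed_time", "rise_time", "sleep_latency", "waso", "nap_days", "nap_duration",
    "workdays", "work_arrival", "work_departure", "occupational_sb_vas",
    "occupational_mvpa_flag", "occupational_mvpa_days", "occupational_mvpa_duration",
    "commute_duration", "commute_sb_vas", "commute_mvpa_duration",
    "other_sb_duration", "other_mvpa_days", "other_mvpa_duration"
  )
}

check_dabq_responses <- function(responses) {
  missing <- setdiff(dabq_response_columns(), names(responses))
  if (length(missing)) {
    stop("response table lacks columns: ", paste(missing, collapse = ", "))
  }
  vas <- c(responses$occupational_sb_vas, responses$commute_sb_vas)
  if (any(vas < 0 | vas > 1, na.rm = TRUE)) stop("VAS proportions must lie in [0, 1]")
  days <- cbind(responses$nap_days, responses$workdays,
                responses$occupational_mvpa_days, responses$other_mvpa_days)
  if (any(days < 0 | days > 7, na.rm = TRUE)) stop("day counts must lie in [0, 7]")
  dur <- cbind(responses$sleep_latency, responses$waso, responses$nap_duration,
               responses$occupational_mvpa_duration, responses$commute_duration,
               responses$commute_mvpa_duration, responses$other_sb_duration,
               responses$other_mvpa_duration)
  if (any(dur < 0, na.rm = TRUE)) stop("durations must be non-negative")
  invisible(TRUE)
}
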