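#' Cohort simulation settings
#'
#' Defines the population from which synthetic validation cohorts are drawn:
#' latent weekly 24-h compositions per participant, occasion-specific
#' questionnaire measurement error, and the device measurement model
#' (persistent construct discrepancy, range attenuation, additive bias and
#' day-level noise), plus diary jitter, naps, boundary bursts and non-wear.
#'
#' Population means default to roughly 443/547/419/31 min/day for
#' sleep/SB/LPA/MVPA (working adults; LPA closes the day). Between-subject
#' and test-retest error SDs default to values whose implied true
#' test-retest ICC sigma_b^2 / (sigma_b^2 + sigma_e^2) is about 0.65 for
#' each behaviour. The device model for behaviour b maps the latent value
#' s_b to mu_b + bias_b + lambda_b (s_b + eta_b - mu_b) plus day-level
#' noise, where eta_b ~ N(0, construct_error_sd_b) is a persistent
#' participant-level discrepancy between what the questionnaire and the
#' device measure and lambda_b < 1 compresses the device's between-subject
#' range; the methods vignette derives the defaults. MVPA, strictly
#' positive and right-skewed, uses lognormal latent values and mean-one
#' multiplicative errors (its device mapping is
#' `bias + lambda * latent * eta`); all MVPA SDs are still specified in
#' min/day and converted by exact moment matching.
#'
#' @param n_participants cohort size (>= 2).
#' @param mean_composition named minutes/day for sleep, sb, lpa, mvpa;
#'   must close to 1440.
#' @param between_sd between-subject SD (min/day) for sleep, sb, mvpa
#'   (LPA closes the day).
#' @param test_retest_error_sd occasion-specific questionnaire error SD
#'   (min/day) for sleep, sb, mvpa.
#' @param device_error_sd day-level device noise SD (min/day) for sleep,
#'   sb, mvpa.
#' @param device_bias additive device bias (min/day) for sleep, sb, mvpa;
#'   positive means the device reads higher than the questionnaire truth.
#' @param device_attenuation multiplicative compression of between-subject
#'   spread in the device measurement, per behaviour (1 = none).
#' @param construct_error_sd SD (min/day) of the persistent participant-level
#'   questionnaire-vs-device construct discrepancy.
#' @param diary_jitter_sd SD (min) of diary bed/wake time error.
#' @param nap_probability per-day probability of a daytime nap.
#' @param burst_probability per-night probability of an upright burst just
#'   after getting into bed.
#' @param night_interruption_probability per-night probability of a brief
#'   (2-4 min) upright interruption inside the sleep window.
#' @param nonwear_rate expected non-wear hours/day.
#' @param nonwear_gap_probability per-day probability that a non-wear gap
#'   occurs (gap length then has mean `nonwear_rate / nonwear_gap_probability`
#'   hours, capped at 6 h).
#' @param p_missing_occasion2 probability a participant skips the second
#'   questionnaire occasion.
#' @param p_noncompliant probability a participant wears the device poorly
#'   (long frequent gaps, usually fewer than 5 valid days).
#' @param workday_sb_shift minutes by which workday SB exceeds the weekly
#'   mean (non-workdays compensate; weekly truth is preserved).
#' @param seed integer master seed.
#' @return named list of settings (class `cohort_config`).
#' @export
cohort_config <- function(n_participants = 126,
                          mean_composition = c(sleep = 443, sb = 547, lpa = 419, mvpa = 31),
                          between_sd = c(sleep = 46, sb = 133, mvpa = 31),
                          test_retest_error_sd = c(sleep = 37, sb = 97, mvpa = 22),
                          device_error_sd = c(sleep = 15, sb = 30, mvpa = 8),
                          device_bias = c(sleep = 0, sb = 96, mvpa = 58),
                          device_attenuation = c(sleep = 0.96, sb = 0.33, mvpa = 0.41),
                          construct_error_sd = c(sleep = 28, sb = 215, mvpa = 52),
                          diary_jitter_sd = 10,
                          nap_probability = 0.3,
                          burst_probability = 0.25,
                          night_interruption_probability = 0.3,
                          nonwear_rate = 0.5,
                          nonwear_gap_probability = 0.3,
                          p_missing_occasion2 = 0.095,
                          p_noncompliant = 0.05,
                          workday_sb_shift = 40,
                          seed = 1L) {
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (abs(sum(mean_composition) - 1440) > 1e-6) {
    stop("mean_composition must close to 1440 min")
  }
  sds <- c(between_sd, test_retest_error_sd, device_error_sd,
           construct_error_sd, diary_jitter_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative")
  stopifnot(nonwear_rate >= 0, nap_probability >= 0, nap_probability <= 1)
  out <- as.list(environment())
  class(out) <- "cohort_config"
  out
}

# MVPA is strictly positive and right-skewed, so its latent values, occasion
# errors and construct discrepancies live on a lognormal scale. The config
# still speaks minutes: SDs are converted by exact moment matching, so the
# latent MVPA mean and SD equal the configured values and a zero SD
# degenerates to a constant, exactly as for the normal behaviours.
lnorm_sdlog <- function(sd, mean) {
  if (mean <= 0) return(0)
  sqrt(log(1 + (sd / mean)^2))
}

# sdlog of a mean-one multiplicative error with raw-scale SD `sd` when
# applied to a variable with raw second moment `m2`
mult_sdlog <- function(sd, m2) sqrt(log(1 + sd^2 / m2))

# mean-one lognormal multiplier draws
rmult <- function(n, sdlog) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

# Deterministic 31-bit sub-seed from a participant seed and a stream tag,
# so questionnaire style, occasion noise and device streams are independent
# but reproducible (exact in double arithmetic: values stay far below 2^53).
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + as.numeric(tag) * 40503137) %% 2147483629 + 1)
}

#' Generate a cohort of participants with known latent compositions
#'
#' Latent weekly compositions are drawn by sampling sleep, SB and MVPA from
#' normals (truncated by reject-and-redraw so all four parts stay positive)
#' and closing LPA to 1440 min, mirroring how the questionnaire scoring
#' itself treats LPA as the 24-h remainder.
#'
#' @param config settings from [cohort_config()].
#' @return data.frame of truth profiles: `participant_id`, latent `sleep`,
#'   `sb`, `lpa`, `mvpa`, `workdays`, `shift_work`, `noncompliant`,
#'   `missing_occasion2`, device construct offsets, and a per-participant
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  mu <- config$mean_composition
  sd_b <- config$between_sd
  sdlog_m <- lnorm_sdlog(sd_b[["mvpa"]], mu[["mvpa"]])
  draw <- function(n, centre) cbind(
    sleep = stats::rnorm(n, centre[["sleep"]], sd_b[["sleep"]]),
    sb = stats::rnorm(n, centre[["sb"]], sd_b[["sb"]]),
    mvpa = stats::rlnorm(n, log(centre[["mvpa"]]) - sdlog_m^2 / 2, sdlog_m)
  )
  # plausibility bounds for a weekly-average adult composition; they match
  # the per-day feasibility limits of the event generator so noise-free
  # streams can realize every accepted latent profile exactly
  ok_rows <- function(m, lpa) {
    m[, "sleep"] >= 310 & m[, "sleep"] <= 760 & m[, "sb"] >= 60 &
      m[, "mvpa"] >= 0 & lpa >= 95
  }
  draw_accepted <- function(n, centre) {
    m <- draw(n, centre)
    lpa <- 1440 - rowSums(m)
    bad <- !ok_rows(m, lpa)
    tries <- 0
    while (any(bad) && tries < 1000) {
      m[bad, ] <- draw(sum(bad), centre)
      lpa <- 1440 - rowSums(m)
      bad <- !ok_rows(m, lpa)
      tries <- tries + 1
    }
    if (any(bad)) stop("could not draw positive compositions; check SDs")
    m
  }
  # Rejection truncates the proposal distribution, so drawing centred on the
  # target means would bias the accepted means. A short pilot (fixed internal
  # seed, independent of the cohort seed) shifts the proposal centre until
  # the accepted means hit the configured population means.
  centre <- mu[c("sleep", "sb", "mvpa")]
  set.seed(424243L)
  for (it in 1:3) {
    pilot <- colMeans(draw_accepted(20000, centre))
    centre[["sleep"]] <- centre[["sleep"]] + (mu[["sleep"]] - pilot[["sleep"]])
    centre[["sb"]] <- centre[["sb"]] + (mu[["sb"]] - pilot[["sb"]])
    centre[["mvpa"]] <- centre[["mvpa"]] * mu[["mvpa"]] / pilot[["mvpa"]]
  }
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, n)
  m <- draw_accepted(n, centre)
  lpa <- 1440 - rowSums(m)
  workdays <- sample(c(0L, 3L, 4L, 5L, 6L), n, replace = TRUE,
                     prob = c(0.03, 0.05, 0.12, 0.70, 0.10))
  shift_work <- stats::runif(n) < 0.49
  m2_mvpa <- mu[["mvpa"]]^2 + sd_b[["mvpa"]]^2
  eta <- cbind(
    sleep = stats::rnorm(n, 0, config$construct_error_sd[["sleep"]]),
    sb = stats::rnorm(n, 0, config$construct_error_sd[["sb"]]),
    # multiplicative (mean-one) for MVPA; stored as the multiplier
    mvpa = rmult(n, mult_sdlog(config$construct_error_sd[["mvpa"]], m2_mvpa))
  )
  noncompliant <- stats::runif(n) < config$p_noncompliant
  missing2 <- stats::runif(n) < config$p_missing_occasion2
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    sleep = m[, "sleep"], sb = m[, "sb"], lpa = lpa, mvpa = m[, "mvpa"],
    workdays = workdays, shift_work = shift_work,
    construct_sleep = eta[, "sleep"], construct_sb = eta[, "sb"],
    construct_mvpa = eta[, "mvpa"],
    noncompliant = noncompliant, missing_occasion2 = missing2,
    seed = seeds,
    stringsAsFactors = FALSE
  )
}

# Habitual response style of one participant: bed time, latency, commute,
# workplace hours, nap habit, allocation shares. Drawn from the participant
# seed only, so the two questionnaire occasions share it.
participant_style <- function(profile, config) {
  set.seed(derive_seed(profile$seed, 1))
  list(
    bed_min = sample(seq(21.5 * 60, 24.5 * 60, by = 5), 1) %% 1440,
    latency = sample(5:25, 1),
    waso = sample(0:20, 1),
    nap_days = stats::rbinom(1, 7, config$nap_probability),
    nap_duration = sample(20:60, 1),
    work_arrival = sample(seq(7 * 60, 9 * 60, by = 15), 1),
    work_span = round(stats::rnorm(1, 492, 25)),
    commute_duration = sample(c(10, 20, 30, 40, 60), 1),
    commute_vas = round(stats::runif(1, 0.5, 1), 2),
    occ_sb_share = stats::runif(1, 0.45, 0.7),
    does_occ_mvpa = stats::runif(1) < 0.5,
    occ_mvpa_days = sample(1:5, 1)
  )
}

# Draw one occasion's noisy composition around the latent truth. Sleep and
# SB get independent normal occasion errors; MVPA a mean-one multiplicative
# lognormal error; LPA closes the day. Reject-and-redraw keeps parts in
# plausible positive ranges.
draw_occasion_target <- function(profile, occasion, config) {
  set.seed(derive_seed(profile$seed, 100 + occasion))
  e <- config$test_retest_error_sd
  mu <- config$mean_composition
  tau <- mult_sdlog(e[["mvpa"]],
                    mu[["mvpa"]]^2 + config$between_sd[["mvpa"]]^2)
  for (i in 1:200) {
    s <- profile$sleep + stats::rnorm(1, 0, e[["sleep"]])
    b <- profile$sb + stats::rnorm(1, 0, e[["sb"]])
    m <- profile$mvpa * rmult(1, tau)
    l <- 1440 - s - b - m
    if (s >= 180 && s <= 780 && b >= 30 && l >= 0) {
      return(c(sleep = s, sb = b, mvpa = m))
    }
  }
  c(sleep = profile$sleep, sb = profile$sb, mvpa = profile$mvpa)
}

#' Generate one participant's questionnaire responses for one occasion
#'
#' Constructs item responses (clock times, VAS proportions, day counts and
#' durations) that are mutually consistent and score back -- through
#' [score_dabq()] -- to the participant's latent composition plus
#' occasion-specific measurement error. Habitual items (bed time, commute,
#' workplace hours, naps) are stable within a participant across occasions;
#' only the measurement error differs. "Other" domain durations absorb
#' allocation remainders so the scored composition matches the noisy target
#' to within clock-rounding (under 1 min/day).
#'
#' @param profile one row of [generate_cohort()].
#' @param occasion 1 or 2.
#' @param config settings from [cohort_config()].
#' @return one-row data.frame matching [dabq_response_columns()].
#' @export
generate_dabq_responses <- function(profile, occasion, config = cohort_config()) {
  stopifnot(occasion %in% c(1, 2))
  style <- participant_style(profile, config)
  target <- draw_occasion_target(profile, occasion, config)

  # --- sleep items: pick rise time so time in bed scores back to target
  nap_days <- style$nap_days
  nap_duration <- if (nap_days > 0) style$nap_duration else 0
  nap_daily <- nap_days * nap_duration / 7
  tib <- target[["sleep"]] + style$latency + style$waso - nap_daily
  rise_min <- (style$bed_min + round(tib)) %% 1440

  # --- SB items: occupational share via VAS, commute, remainder to "other"
  workdays <- profile$workdays
  span <- style$work_span
  departure <- (style$work_arrival + span) %% 1440
  cap_occ <- span * workdays / 7
  sb_target <- target[["sb"]]
  commute_sb <- style$commute_duration * style$commute_vas
  commute_vas <- style$commute_vas
  if (cap_occ > 0) {
    occ_vas <- min(1, max(0, round(style$occ_sb_share * sb_target / cap_occ, 2)))
  } else {
    occ_vas <- 0
  }
  occ_sb <- cap_occ * occ_vas
  other_sb <- sb_target - occ_sb - commute_sb
  if (other_sb < 0) {
    commute_vas <- min(1, max(0, round((sb_target - occ_sb) / style$commute_duration, 2)))
    commute_sb <- style$commute_duration * commute_vas
    other_sb <- sb_target - occ_sb - commute_sb
  }
  if (other_sb < 0 && cap_occ > 0) {
    occ_vas <- min(1, max(0, round(sb_target / cap_occ, 2)))
    occ_sb <- cap_occ * occ_vas
    commute_vas <- 0
    commute_sb <- 0
    other_sb <- max(0, sb_target - occ_sb)
  }
  other_sb <- max(0, other_sb)

  # --- MVPA items: integer occupational/commuting pieces, exact remainder
  #     in the daily-average "other" item
  m_target <- target[["mvpa"]]
  occ_days <- min(style$occ_mvpa_days, max(workdays, 0L))
  if (style$does_occ_mvpa && workdays > 0 && m_target >= 3) {
    occ_dur <- floor(min(0.4 * m_target, 60) * 7 / occ_days)
    occ_dur <- max(0, occ_dur)
  } else {
    occ_dur <- 0
  }
  occ_mvpa <- occ_days * occ_dur / 7
  commute_mvpa <- if (m_target >= 3) floor(min(0.2 * m_target, 15)) else 0
  other_mvpa <- max(0, m_target - occ_mvpa - commute_mvpa)

  data.frame(
    participant_id = profile$participant_id,
    occasion = occasion,
    bed_time = format_hhmm(style$bed_min),
    rise_time = format_hhmm(rise_min),
    sleep_latency = style$latency,
    waso = style$waso,
    nap_days = nap_days,
    nap_duration = nap_duration,
    workdays = workdays,
    work_arrival = format_hhmm(style$work_arrival),
    work_departure = format_hhmm(departure),
    occupational_sb_vas = occ_vas,
    occupational_mvpa_flag = if (occ_dur > 0) "yes" else "no",
    occupational_mvpa_days = occ_days,
    occupational_mvpa_duration = occ_dur,
    commute_duration = style$commute_duration,
    commute_sb_vas = commute_vas,
    commute_mvpa_duration = commute_mvpa,
    other_sb_duration = other_sb,
    other_mvpa_days = 7L,
    other_mvpa_duration = other_mvpa,
    stringsAsFactors = FALSE
  )
}

#' Generate a questionnaire response table for a whole cohort
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param occasion 1 or 2; on occasion 2, participants flagged
#'   `missing_occasion2` are omitted (non-response).
#' @param config settings from [cohort_config()].
#' @return data.frame, one row per responding participant.
#' @export
generate_dabq_table <- function(cohort, occasion, config = cohort_config()) {
  keep <- if (occasion == 2) !cohort$missing_occasion2 else rep(TRUE, nrow(cohort))
  rows <- lapply(which(keep), function(i) {
    generate_dabq_responses(cohort[i, , drop = FALSE], occasion, config)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
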