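# Event-stream synthesis: builds a plausible activPAL-style events file per
# participant-day that tiles noon-to-noon, embeds a nightly time-in-bed
# window, naps as daytime sitting, optional upright bursts at the sleep
# boundary, brief night interruptions, and non-wear gaps -- while keeping
# the exact per-day behaviour totals available as ground truth.

# Split waking totals (sitting, supra-threshold stepping, other upright)
# between the afternoon (length a seconds) and morning (length m seconds)
# segments, preserving totals exactly.
split_waking_totals <- function(sit, supra, upright, a, m) {
  stopifnot(abs(sit + supra + upright - (a + m)) < 1)
  fa <- a / (a + m)
  sitA <- min(sit, round(sit * fa))
  supraA <- min(supra, round(supra * fa))
  upA <- a - sitA - supraA
  if (upA < 0) {
    take <- min(supraA, -upA); supraA <- supraA - take; upA <- upA + take
  }
  if (upA < 0) {
    take <- min(sitA, -upA); sitA <- sitA - take; upA <- upA + take
  }
  if (upA > upright) {
    excess <- upA - upright
    upA <- upright
    add_sit <- min(excess, sit - sitA)
    sitA <- sitA + add_sit
    supraA <- supraA + (excess - add_sit)
  }
  sitM <- sit - sitA; supraM <- supra - supraA; upM <- upright - upA
  stopifnot(sitA >= 0, supraA >= 0, upA >= 0, sitM >= 0, supraM >= 0, upM > -1)
  upM <- max(0, upM)
  list(A = c(sit = sitA, supra = supraA, up = upA),
       M = c(sit = sitM, supra = supraM, up = upM))
}

# Tile one waking segment [t0, t0 + len) with events realizing the given
# totals (seconds). Upright time is split 60/40 into standing and
# sub-threshold stepping. Sitting is chunked so that consecutive sitting
# runs are separated by more than the 15-min merge budget wherever upright
# time allows. An optional non-wear gap is inserted mid-segment.
# `stand_first` makes the segment open with upright activity (morning rise).
tile_segment <- function(t0, totals, gap_s = 0, stand_first = FALSE,
                         sub_cadence = 75, supra_cadence = 115) {
  sit <- unname(totals["sit"]); supra <- unname(totals["supra"])
  up <- unname(totals["up"])
  stand <- round(up * 0.6); sub <- up - stand
  len <- sit + supra + up
  n_cycles <- max(1, floor(up / 960))
  sit_chunk <- max(600, ceiling(sit / n_cycles))
  stand_chunk <- max(300, ceiling(stand / n_cycles))
  sub_chunk <- max(300, ceiling(sub / n_cycles))
  supra_chunk <- max(180, ceiling(supra / max(1, n_cycles)))
  gap_at <- if (gap_s > 0) len / 2 else Inf

  rows <- list(); t <- t0; emitted <- 0; gap_done <- gap_s == 0
  emit <- function(dur, cls, cad) {
    rows[[length(rows) + 1]] <<- data.frame(start = t, duration = dur,
                                            activity_class = cls, cadence = cad)
    t <<- t + dur
    emitted <<- emitted + dur
  }
  take <- function(rem, chunk) min(rem, chunk)
  first <- TRUE
  while (sit + stand + sub + supra > 0) {
    if (!gap_done && emitted >= gap_at) {
      t <- t + gap_s
      gap_done <- TRUE
    }
    if (stand_first && first) {
      if (stand > 0) { d <- take(stand, stand_chunk); emit(d, CLASS_STAND, 0); stand <- stand - d }
      if (sub > 0) { d <- take(sub, sub_chunk); emit(d, CLASS_STEP, sub_cadence); sub <- sub - d }
      first <- FALSE
      next
    }
    first <- FALSE
    if (sit > 0) { d <- take(sit, sit_chunk); emit(d, CLASS_SIT, 0); sit <- sit - d }
    if (stand > 0) { d <- take(stand, stand_chunk); emit(d, CLASS_STAND, 0); stand <- stand - d }
    if (sub > 0) { d <- take(sub, sub_chunk); emit(d, CLASS_STEP, sub_cadence); sub <- sub - d }
    if (supra > 0) { d <- take(supra, supra_chunk); emit(d, CLASS_STEP, supra_cadence); supra <- supra - d }
  }
  if (!gap_done) t <- t + gap_s
  do.call(rbind, rows)
}

#' Generate a device event stream and sleep diary for one participant
#'
#' Emits non-overlapping, time-ordered events tiling each noon-to-noon
#' monitoring day except explicit non-wear gaps. Each night holds one long
#' sitting/lying block, optionally preceded by an in-bed upright burst and
#' interrupted by a brief night-time break; the diary carries the intended
#' bed and wake times with jitter plus nap durations. The per-day
#' device-truth composition (what ideal processing should recover) is
#' returned alongside.
#'
#' @param profile one row of [generate_cohort()].
#' @param config settings from [cohort_config()].
#' @param n_days number of monitoring days (>= 1).
#' @param start_date first monitoring date (the day whose noon starts the
#'   first window).
#' @return list with `events`, `diary` and `truth` data.frames; times are
#'   POSIXct (UTC).
#' @export
generate_event_stream <- function(profile, config = cohort_config(),
                                  n_days = 7, start_date = "2022-03-07") {
  stopifnot(n_days >= 1)
  style <- participant_style(profile, config)
  set.seed(derive_seed(profile$seed, 300))
  origin <- as.POSIXct(paste(start_date, "12:00:00"), tz = "UTC")
  t_origin <- as.numeric(origin)

  mu <- config$mean_composition
  lam <- config$device_attenuation
  bias <- config$device_bias
  # persistent device-side latent value per behaviour
  dev_latent <- c(
    sleep = mu[["sleep"]] + bias[["sleep"]] +
      lam[["sleep"]] * (profile$sleep + profile$construct_sleep - mu[["sleep"]]),
    sb = mu[["sb"]] + bias[["sb"]] +
      lam[["sb"]] * (profile$sb + profile$construct_sb - mu[["sb"]]),
    # MVPA maps multiplicatively: construct_mvpa is a mean-one multiplier
    mvpa = bias[["mvpa"]] + lam[["mvpa"]] * profile$mvpa * profile$construct_mvpa
  )
  workdays <- profile$workdays
  is_work <- seq_len(n_days) <= workdays  # week starts Monday

  if (profile$noncompliant) {
    p_gap <- 0.85; gap_mean_h <- 5
  } else {
    p_gap <- config$nonwear_gap_probability
    gap_mean_h <- if (p_gap > 0) config$nonwear_rate / p_gap else 0
  }

  ev_rows <- list(); diary_rows <- list(); truth_rows <- list()
  for (d in seq_len(n_days)) {
    T0 <- t_origin + (d - 1) * 86400
    e <- config$device_error_sd
    sleep_d <- dev_latent[["sleep"]] + stats::rnorm(1, 0, e[["sleep"]])
    sb_d <- dev_latent[["sb"]] + stats::rnorm(1, 0, e[["sb"]]) +
      config$workday_sb_shift * (is_work[d] - workdays / 7)
    mvpa_d <- max(0, dev_latent[["mvpa"]] + stats::rnorm(1, 0, e[["mvpa"]]))
    sleep_d <- min(780, max(300, sleep_d))
    sb_d <- max(60, sb_d)
    lpa_d <- 1440 - sleep_d - sb_d - mvpa_d
    if (lpa_d < 90) {         # keep enough upright time to separate sitting runs
      sb_d <- sb_d - (90 - lpa_d)
      lpa_d <- 90
    }

    nap_d <- if (stats::runif(1) < config$nap_probability) sample(20:60, 1) else 0
    nap_d <- min(nap_d, max(0, sleep_d - 280))
    night_s <- round((sleep_d - nap_d) * 60)

    # sleep window placement
    onset_clock <- (style$bed_min + stats::rnorm(1, 0, 15)) %% 1440
    onset_abs <- T0 + ((onset_clock - config_hour_min()) %% 1440) * 60
    latest <- T0 + 86400 - night_s - 45 * 60
    onset_abs <- min(onset_abs, latest)
    onset_abs <- max(onset_abs, T0 + 4 * 3600)
    onset_abs <- round(onset_abs)
    offset_abs <- onset_abs + night_s

    # optional upright burst just after getting into bed
    has_burst <- stats::runif(1) < config$burst_probability
    pre_sit_s <- if (has_burst) sample(3:8, 1) * 60 else 0
    preblock_s <- if (has_burst) pre_sit_s + 120 else 0
    attempt <- onset_abs - preblock_s

    lenA_raw <- attempt - T0
    lenM <- T0 + 86400 - offset_abs

    # non-wear gap (afternoon)
    gap_s <- 0
    if (p_gap > 0 && stats::runif(1) < p_gap) {
      gap_s <- round(min(6 * 3600, stats::rexp(1, 1 / (gap_mean_h * 3600))))
      gap_s <- min(gap_s, round(0.6 * lenA_raw))
    }
    lenA <- lenA_raw - gap_s

    sit_tot <- round((sb_d + nap_d) * 60) - pre_sit_s
    supra_tot <- round(mvpa_d * 60)
    # the gap removes waking behaviours proportionally, so reallocation
    # downstream can restore them; upright time absorbs rounding
    if (gap_s > 0) {
      f <- (lenA + lenM) / (lenA_raw + lenM)
      sit_tot <- round(sit_tot * f)
      supra_tot <- round(supra_tot * f)
    }
    upright_tot <- (lenA + lenM) - sit_tot - supra_tot
    if (upright_tot < 0) {  # degenerate day; shrink sitting to fit
      sit_tot <- sit_tot + upright_tot
      upright_tot <- 0
    }

    parts <- split_waking_totals(sit_tot, supra_tot, upright_tot, lenA, lenM)
    ev_day <- list(tile_segment(T0, parts$A, gap_s = gap_s))

    if (has_burst) {
      ev_day[[length(ev_day) + 1]] <- data.frame(
        start = c(attempt, attempt + pre_sit_s, attempt + pre_sit_s + 60),
        duration = c(pre_sit_s, 60, 60),
        activity_class = c(CLASS_SIT, CLASS_STAND, CLASS_STEP),
        cadence = c(0, 0, 80)
      )
    }

    # night: one long sitting/lying block, optionally briefly interrupted
    if (stats::runif(1) < config$night_interruption_probability &&
        night_s > 2 * 3600) {
      brk <- sample(120:240, 1)
      at <- onset_abs + round(stats::runif(1, 0.3, 0.7) * night_s)
      ev_day[[length(ev_day) + 1]] <- data.frame(
        start = c(onset_abs, at, at + brk),
        duration = c(at - onset_abs, brk, offset_abs - at - brk),
        activity_class = c(CLASS_SIT, CLASS_STAND, CLASS_SIT),
        cadence = 0
      )
    } else {
      ev_day[[length(ev_day) + 1]] <- data.frame(
        start = onset_abs, duration = night_s,
        activity_class = CLASS_SIT, cadence = 0
      )
    }

    ev_day[[length(ev_day) + 1]] <- tile_segment(offset_abs, parts$M,
                                                 stand_first = TRUE)
    ev_rows[[d]] <- do.call(rbind, ev_day)

    jit <- function() round(stats::rnorm(1, 0, config$diary_jitter_sd) * 60)
    diary_rows[[d]] <- data.frame(
      date = as.Date(start_date) + (d - 1),
      intended_onset = attempt + jit(),
      wake_time = offset_abs + jit(),
      nap_minutes = nap_d
    )
    # device-truth: what ideal processing recovers (nap folded back to sleep)
    sleep_truth <- night_s / 60 + nap_d
    truth_rows[[d]] <- data.frame(
      day = d,
      sleep = sleep_truth,
      sb = sb_d,
      mvpa = mvpa_d,
      nonwear = gap_s / 60
    )
  }

  events <- do.call(rbind, c(ev_rows, list(make.row.names = FALSE)))
  events <- data.frame(participant_id = profile$participant_id, events,
                       stringsAsFactors = FALSE)
  events$start <- as.POSIXct(events$start, origin = "1970-01-01", tz = "UTC")
  diary <- do.call(rbind, c(diary_rows, list(make.row.names = FALSE)))
  diary <- data.frame(participant_id = profile$participant_id, diary,
                      stringsAsFactors = FALSE)
  diary$intended_onset <- as.POSIXct(diary$intended_onset, origin = "1970-01-01", tz = "UTC")
  diary$wake_time <- as.POSIXct(diary$wake_time, origin = "1970-01-01", tz = "UTC")
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  truth$lpa <- 1440 - truth$sleep - truth$sb - truth$mvpa
  truth <- data.frame(participant_id = profile$participant_id,
                      truth[, c("day", "sleep", "sb", "lpa", "mvpa", "nonwear")],
                      stringsAsFactors = FALSE)
  list(events = events, diary = diary, truth = truth)
}

# minutes past midnight at which monitoring days begin (noon)
config_hour_min <- function() 720

#' Generate a complete synthetic validation study
#'
#' Draws a cohort, both questionnaire occasions (with occasion-2
#' non-response), and a week of device events, diaries and per-day ground
#' truth for every participant.
#'
#' @param config settings from [cohort_config()].
#' @param n_days monitoring days per participant.
#' @return list with `cohort`, `dabq1`, `dabq2`, `events`, `diaries`,
#'   `truth`.
#' @export
generate_study <- function(config = cohort_config(), n_days = 7) {
  cohort <- generate_cohort(config)
  dabq1 <- generate_dabq_table(cohort, 1, config)
  dabq2 <- generate_dabq_table(cohort, 2, config)
  ev <- list(); di <- list(); tr <- list()
  for (i in seq_len(nrow(cohort))) {
    s <- generate_event_stream(cohort[i, , drop = FALSE], config, n_days)
    ev[[i]] <- s$events; di[[i]] <- s$diary; tr[[i]] <- s$truth
  }
  list(
    cohort = cohort,
    dabq1 = dabq1, dabq2 = dabq2,
    events = do.call(rbind, c(ev, list(make.row.names = FALSE))),
    diaries = do.call(rbind, c(di, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(tr, list(make.row.names = FALSE)))
  )
}
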