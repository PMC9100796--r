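#' Configuration for event-stream processing
#'
#' Tunable parameters of the device-processing chain. Defaults follow the
#' processing protocol: a valid day has more than 20 h of wear under a 24-h
#' protocol allowing up to 4 h of non-wear; the longest sitting/lying run is
#' merged across interruptions totalling at most 15 min; diary/device sleep
#' fusion looks 20 min past the diary bed time; an upright "burst" is at
#' least 1 min of cumulative standing/stepping within any 5-min span;
#' stepping at or above 100 steps/min (~3 METs) counts as MVPA; days run
#' noon to noon so each night belongs to one day.
#'
#' @param burst_window_min sliding-window length (min) for burst detection.
#' @param burst_min_upright_min cumulative upright minutes within the window
#'   needed to call a burst.
#' @param interruption_budget_min total interruption minutes mergeable into
#'   the longest sitting/lying run.
#' @param onset_window_min look-ahead window (min) after the diary bed time
#'   in which an upright burst overrides the diary.
#' @param offset_min_sit_min minimum preceding sitting/lying minutes for a
#'   burst to qualify as the morning rise.
#' @param cadence_cutpoint steps/min at or above which stepping is MVPA.
#' @param day_boundary_hour local hour at which monitoring days start.
#' @param wear_valid_min minimum wear minutes for a valid day (exclusive).
#' @param min_valid_days valid days required to include a participant.
#' @return named list of settings.
#' @export
activpal_config <- function(burst_window_min = 5,
                            burst_min_upright_min = 1,
                            interruption_budget_min = 15,
                            onset_window_min = 20,
                            offset_min_sit_min = 60,
                            cadence_cutpoint = 100,
                            day_boundary_hour = 12,
                            wear_valid_min = 1200,
                            min_valid_days = 5) {
  stopifnot(burst_window_min > 0, burst_min_upright_min > 0,
            interruption_budget_min >= 0, onset_window_min > 0,
            offset_min_sit_min >= 0, cadence_cutpoint > 0,
            day_boundary_hour >= 0, day_boundary_hour < 24,
            wear_valid_min > 0, min_valid_days >= 1)
  list(
    burst_window_min = burst_window_min,
    burst_min_upright_min = burst_min_upright_min,
    interruption_budget_min = interruption_budget_min,
    onset_window_min = onset_window_min,
    offset_min_sit_min = offset_min_sit_min,
    cadence_cutpoint = cadence_cutpoint,
    day_boundary_hour = day_boundary_hour,
    wear_valid_min = wear_valid_min,
    min_valid_days = min_valid_days
  )
}

# Activity class codes used throughout: 0 sitting/lying, 1 standing, 2 stepping.
CLASS_SIT <- 0L
CLASS_STAND <- 1L
CLASS_STEP <- 2L

# Coerce an event table to numeric-second internal form, sorted and checked
# for overlap. Accepts POSIXct or numeric start times and either integer
# codes or the labels sitting_lying/standing/stepping.
normalize_events <- function(events) {
  stopifnot(all(c("start", "duration") %in% names(events)))
  start <- as.numeric(events$start)
  duration <- as.numeric(events$duration)
  if (any(duration <= 0)) stop("event durations must be positive")
  cls <- events$activity_class
  if (is.character(cls) || is.factor(cls)) {
    cls <- match(as.character(cls), c("sitting_lying", "standing", "stepping")) - 1L
    if (anyNA(cls)) stop("unknown activity_class label")
  }
  cls <- as.integer(cls)
  if (!all(cls %in% c(CLASS_SIT, CLASS_STAND, CLASS_STEP))) {
    stop("activity_class must be 0 (sitting/lying), 1 (standing) or 2 (stepping)")
  }
  cad <- if ("cadence" %in% names(events)) as.numeric(events$cadence) else numeric(length(start))
  cad[is.na(cad)] <- 0
  o <- order(start)
  ev <- data.frame(start = start[o], duration = duration[o],
                   activity_class = cls[o], cadence = cad[o])
  ev$end <- ev$start + ev$duration
  if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)] - 0.5)) {
    stop("events overlap within a participant")
  }
  ev
}

# Merge a set of [start, end] intervals that touch (gap <= tol seconds).
merge_intervals <- function(start, end, tol = 0.5) {
  if (length(start) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + tol) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

#' Detect bursts of upright events
#'
#' A burst is any cluster of standing/stepping events accumulating at least
#' `burst_min_upright_min` minutes of upright time within a sliding window
#' of `burst_window_min` minutes. Qualifying upright intervals closer than
#' one window length are grouped into a single burst spanning from the first
#' to the last upright event of the group. Isolated few-second posture
#' flickers therefore do not register.
#'
#' @param events event table (see [normalize_events()] column contract).
#' @param config list from [activpal_config()].
#' @return data.frame with columns `start`, `end` (numeric seconds), one row
#'   per burst, time-ordered.
#' @export
find_upright_bursts <- function(events, config = activpal_config()) {
  ev <- normalize_events(events)
  up <- ev[ev$activity_class != CLASS_SIT, , drop = FALSE]
  iv <- merge_intervals(up$start, up$end)
  m <- nrow(iv)
  if (m == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  win <- config$burst_window_min * 60
  need <- config$burst_min_upright_min * 60
  # Window anchored at each upright interval start; the maximum cumulative
  # upright time over all windows is attained at one of these anchors.
  qualifies <- logical(m)
  for (i in seq_len(m)) {
    w0 <- iv$start[i]; w1 <- w0 + win
    ov <- pmax(0, pmin(iv$end, w1) - pmax(iv$start, w0))
    if (sum(ov) >= need - 1e-9) {
      qualifies <- qualifies | (iv$end > w0 & iv$start < w1)
    }
  }
  iv <- iv[qualifies, , drop = FALSE]
  if (nrow(iv) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  merge_intervals(iv$start, iv$end, tol = win)
}

#' Detect the candidate time-in-bed window for one monitoring day
#'
#' Finds the longest run of sitting/lying events that can be merged across
#' upright interruptions (or gaps) totalling at most the interruption budget
#' (default 15 min), emulating how the device software identifies the
#' longest sitting/lying event of each day while allowing for bathroom
#' breaks. Ties are broken by the earliest start.
#'
#' @param events event table.
#' @param window optional numeric `c(start, end)` in seconds restricting the
#'   search (the monitoring day); events are clipped to it.
#' @param config list from [activpal_config()].
#' @return list with `onset` and `offset` (numeric seconds), or `NULL` when
#'   the window holds no sitting/lying events.
#' @export
detect_time_in_bed <- function(events, window = NULL, config = activpal_config()) {
  ev <- normalize_events(events)
  if (!is.null(window)) {
    ev$start <- pmax(ev$start, window[1])
    ev$end <- pmin(ev$end, window[2])
    ev <- ev[ev$end - ev$start > 0, , drop = FALSE]
  }
  sit <- ev[ev$activity_class == CLASS_SIT, , drop = FALSE]
  runs <- merge_intervals(sit$start, sit$end)
  m <- nrow(runs)
  if (m == 0) return(NULL)
  budget <- config$interruption_budget_min * 60
  best_span <- -Inf; best <- NULL
  for (i in seq_len(m)) {
    interruption <- 0
    for (j in i:m) {
      if (j > i) {
        interruption <- interruption + (runs$start[j] - runs$end[j - 1])
        if (interruption > budget + 1e-9) break
      }
      span <- runs$end[j] - runs$start[i]
      if (span > best_span + 1e-9) {
        best_span <- span
        best <- list(onset = runs$start[i], offset = runs$end[j])
      }
    }
  }
  best
}

#' Fuse diary and device information into the sleep onset
#'
#' Diary bed time is used unless an upright burst occurs within the
#' following 20 min (configurable), in which case onset moves to the start
#' of the first sitting/lying event after the last such burst. A missing
#' diary falls back to the candidate window onset.
#'
#' @param diary_onset diary bed time (numeric seconds) or `NA`.
#' @param events event table for the night/day.
#' @param candidate candidate window from [detect_time_in_bed()].
#' @param config list from [activpal_config()].
#' @return list with `time` (numeric seconds) and `source` ("diary" or
#'   "event").
#' @export
fuse_sleep_onset <- function(diary_onset, events, candidate,
                             config = activpal_config()) {
  if (is.null(candidate)) stop("candidate sleep window is required")
  if (is.na(diary_onset)) {
    return(list(time = candidate$onset, source = "event"))
  }
  diary_onset <- as.numeric(diary_onset)
  bursts <- find_upright_bursts(events, config)
  win_end <- diary_onset + config$onset_window_min * 60
  hit <- bursts$end > diary_onset & bursts$start <= win_end
  if (!any(hit)) {
    return(list(time = diary_onset, source = "diary"))
  }
  last_end <- max(bursts$end[hit])
  ev <- normalize_events(events)
  sit <- ev[ev$activity_class == CLASS_SIT & ev$start >= last_end - 0.5, , drop = FALSE]
  if (nrow(sit) == 0) {
    return(list(time = candidate$onset, source = "event"))
  }
  list(time = min(sit$start), source = "event")
}

#' Fuse diary and device information into the sleep offset
#'
#' The morning rise is the first upright burst after the sleep onset that
#' follows more than `offset_min_sit_min` minutes of sitting/lying and
#' after which sitting/lying does not resume for that long again before
#' the next burst -- so a brief night-time bathroom break, which both
#' follows and precedes hours of lying, is not mistaken for the rise.
#' Diary wake time is used when it precedes the qualifying burst; otherwise
#' the offset is the end of the last sitting/lying event before the burst.
#' With no qualifying burst the diary is used; a missing diary falls back
#' to the candidate window offset.
#'
#' @param diary_wake diary wake time (numeric seconds) or `NA`.
#' @param events event table.
#' @param candidate candidate window from [detect_time_in_bed()].
#' @param onset resolved sleep onset (numeric seconds).
#' @param config list from [activpal_config()].
#' @return list with `time` and `source` ("diary" or "event").
#' @export
fuse_sleep_offset <- function(diary_wake, events, candidate, onset,
                              config = activpal_config()) {
  if (is.null(candidate)) stop("candidate sleep window is required")
  if (is.na(diary_wake)) {
    return(list(time = candidate$offset, source = "event"))
  }
  diary_wake <- as.numeric(diary_wake)
  ev <- normalize_events(events)
  bursts <- find_upright_bursts(events, config)
  sit <- ev[ev$activity_class == CLASS_SIT, , drop = FALSE]
  sit_between <- function(a, b) {
    if (b <= a) 0 else sum(pmax(0, pmin(sit$end, b) - pmax(sit$start, a)))
  }
  cand <- bursts[bursts$start > onset, , drop = FALSE]
  need <- config$offset_min_sit_min * 60
  qual <- NULL
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      # sitting/lying accumulated since the previous burst (or the onset)
      from <- if (i > 1) cand$end[i - 1] else onset
      if (sit_between(from, cand$start[i]) <= need) next
      # and sitting must not simply resume until the next burst
      until <- if (i < nrow(cand)) cand$start[i + 1] else Inf
      if (sit_between(cand$end[i], until) > need) next
      qual <- cand[i, ]
      break
    }
  }
  if (is.null(qual)) {
    return(list(time = diary_wake, source = "diary"))
  }
  if (diary_wake < qual$start) {
    return(list(time = diary_wake, source = "diary"))
  }
  before <- sit[sit$end <= qual$start + 0.5, , drop = FALSE]
  if (nrow(before) == 0) {
    return(list(time = candidate$offset, source = "event"))
  }
  list(time = max(before$end), source = "event")
}

#' Classify waking time into SB, LPA and MVPA for one day
#'
#' Outside the resolved sleep window, sitting/lying counts as sedentary
#' behaviour; stepping at or above the cadence cut-point (~3 METs) counts as
#' MVPA; uncovered waking time is non-wear; LPA is the waking remainder
#' (standing and sub-threshold stepping). Events straddling the sleep or
#' day boundaries are split at the boundary.
#'
#' @param events event table.
#' @param onset,offset resolved sleep window (numeric seconds).
#' @param window numeric `c(start, end)` of the monitoring day in seconds.
#' @param config list from [activpal_config()].
#' @return list of minutes: `sleep`, `sb`, `lpa`, `mvpa`, `nonwear`.
#' @export
classify_waking <- function(events, onset, offset, window,
                            config = activpal_config()) {
  ev <- normalize_events(events)
  onset <- max(window[1], min(as.numeric(onset), window[2]))
  offset <- max(onset, min(as.numeric(offset), window[2]))
  waking <- rbind(c(window[1], onset), c(offset, window[2]))
  sb_s <- 0; mvpa_s <- 0; covered_s <- 0
  for (r in seq_len(nrow(waking))) {
    a <- waking[r, 1]; b <- waking[r, 2]
    if (b - a <= 0) next
    ov <- pmax(0, pmin(ev$end, b) - pmax(ev$start, a))
    covered_s <- covered_s + sum(ov)
    sb_s <- sb_s + sum(ov[ev$activity_class == CLASS_SIT])
    mvpa_s <- mvpa_s + sum(ov[ev$activity_class == CLASS_STEP &
                                ev$cadence >= config$cadence_cutpoint])
  }
  waking_s <- sum(pmax(0, waking[, 2] - waking[, 1]))
  nonwear_s <- max(0, waking_s - covered_s)
  lpa_s <- waking_s - sb_s - mvpa_s - nonwear_s
  list(
    sleep = (offset - onset) / 60,
    sb = sb_s / 60, lpa = lpa_s / 60, mvpa = mvpa_s / 60,
    nonwear = nonwear_s / 60
  )
}

#' Transfer diary naps from sedentary behaviour to sleep
#'
#' Diary nap minutes are added to sleep and deducted from the day's SB
#' (naps appear as daytime sitting in the event stream). If the nap exceeds
#' available SB, only what exists is transferred and the day is flagged.
#'
#' @param summary one-day list or data.frame row with `sleep` and `sb`.
#' @param nap_minutes diary nap duration for the day.
#' @return the summary with adjusted `sleep`/`sb` and a logical
#'   `nap_overshoot` flag.
#' @export
adjust_naps <- function(summary, nap_minutes) {
  nap_minutes <- ifelse(is.na(nap_minutes), 0, nap_minutes)
  if (nap_minutes < 0) stop("nap_minutes must be non-negative")
  transfer <- min(nap_minutes, summary$sb)
  summary$sleep <- summary$sleep + transfer
  summary$sb <- summary$sb - transfer
  summary$nap_overshoot <- nap_minutes > transfer
  summary
}

#' Non-wear accounting for one day
#'
#' @param nonwear_min non-wear minutes detected for the day.
#' @param config list from [activpal_config()].
#' @return list with `nonwear`, `wear` and `valid` (wear strictly above the
#'   20-h threshold).
#' @export
account_nonwear <- function(nonwear_min, config = activpal_config()) {
  wear <- 1440 - nonwear_min
  list(nonwear = nonwear_min, wear = wear, valid = wear > config$wear_valid_min)
}

#' Proportionally reallocate non-wear time to waking behaviours
#'
#' SB, LPA and MVPA are scaled by `(waking + nonwear) / waking`; sleep is
#' untouched. Afterwards the four behaviours close to 1440 min. A day with
#' no classified waking time cannot be reallocated and is invalidated.
#'
#' @param summary one-day list or data.frame row with `sleep`, `sb`, `lpa`,
#'   `mvpa`, `nonwear` and `valid`.
#' @return the summary with scaled behaviours and `nonwear = 0`.
#' @export
reallocate_nonwear <- function(summary) {
  if (summary$nonwear <= 0) return(summary)
  waking <- summary$sb + summary$lpa + summary$mvpa
  if (waking <= 0) {
    summary$valid <- FALSE
    return(summary)
  }
  scale <- (waking + summary$nonwear) / waking
  summary$sb <- summary$sb * scale
  summary$lpa <- summary$lpa * scale
  summary$mvpa <- summary$mvpa * scale
  summary$nonwear <- 0
  summary
}

#' Average daily summaries into a weekly composition
#'
#' Arithmetic mean over valid days only; a participant with fewer than
#' `min_valid_days` valid days is excluded (`valid = FALSE`).
#'
#' @param daily data.frame of day summaries with behaviour columns and a
#'   `valid` flag.
#' @param min_valid_days inclusion threshold.
#' @return one-row data.frame: behaviours, `n_valid_days`, `valid`.
#' @export
average_week <- function(daily, min_valid_days = 5) {
  if (nrow(daily) == 0) stop("no daily summaries supplied")
  ok <- daily[daily$valid, , drop = FALSE]
  n_ok <- nrow(ok)
  if (n_ok < min_valid_days) {
    return(data.frame(sleep = NA_real_, sb = NA_real_, lpa = NA_real_,
                      mvpa = NA_real_, n_valid_days = n_ok, valid = FALSE))
  }
  data.frame(
    sleep = mean(ok$sleep), sb = mean(ok$sb),
    lpa = mean(ok$lpa), mvpa = mean(ok$mvpa),
    n_valid_days = n_ok, valid = TRUE
  )
}

# Process one monitoring day (window in numeric seconds) for one participant.
process_day <- function(ev, diary_row, window, config) {
  flags <- character(0)
  day <- list(sleep = 0, sb = 0, lpa = 0, mvpa = 0, nonwear = 1440,
              onset = NA_real_, offset = NA_real_,
              onset_source = NA_character_, offset_source = NA_character_,
              nap_overshoot = FALSE, valid = FALSE)
  in_win <- ev[ev$end > window[1] & ev$start < window[2], , drop = FALSE]
  if (nrow(in_win) == 0) {
    day$flags <- "no_events"
    return(day)
  }
  candidate <- detect_time_in_bed(in_win, window = window, config = config)
  if (is.null(candidate)) {
    day$flags <- "no_sleep_window"
    return(day)
  }
  diary_onset <- if (is.null(diary_row)) NA_real_ else as.numeric(diary_row$intended_onset)
  diary_wake <- if (is.null(diary_row)) NA_real_ else as.numeric(diary_row$wake_time)
  nap_min <- if (is.null(diary_row)) 0 else diary_row$nap_minutes
  if (is.null(diary_row)) flags <- c(flags, "missing_diary")

  on <- fuse_sleep_onset(diary_onset, in_win, candidate, config)
  off <- fuse_sleep_offset(diary_wake, in_win, candidate, on$time, config)
  if (off$time <= on$time) {
    # degenerate fused window; fall back to the device candidate
    on <- list(time = candidate$onset, source = "event")
    off <- list(time = candidate$offset, source = "event")
    flags <- c(flags, "fusion_degenerate")
  }

  parts <- classify_waking(in_win, on$time, off$time, window, config)
  acct <- account_nonwear(parts$nonwear, config)
  parts$valid <- acct$valid
  parts <- adjust_naps(parts, nap_min)
  if (parts$nap_overshoot) flags <- c(flags, "nap_overshoot")
  if (parts$valid) parts <- reallocate_nonwear(parts)

  list(sleep = parts$sleep, sb = parts$sb, lpa = parts$lpa, mvpa = parts$mvpa,
       nonwear = acct$nonwear, wear = acct$wear,
       onset = on$time, offset = off$time,
       onset_source = on$source, offset_source = off$source,
       nap_overshoot = parts$nap_overshoot, valid = parts$valid,
       flags = paste(flags, collapse = ";"))
}

#' Process event streams and sleep diaries into daily and weekly estimates
#'
#' Runs the full device-processing chain for every participant: candidate
#' time-in-bed detection, diary fusion of sleep onset/offset, waking
#' classification by posture and cadence, nap transfer, non-wear accounting
#' and reallocation, and valid-day weekly averaging.
#'
#' @param events data.frame with columns `participant_id`, `start` (POSIXct
#'   or numeric seconds), `duration` (s), `activity_class`, `cadence`.
#' @param diaries data.frame with columns `participant_id`,
#'   `intended_onset`, `wake_time` (POSIXct or numeric seconds),
#'   `nap_minutes`.
#' @param config list from [activpal_config()].
#' @return list with `daily` (one row per participant-day) and `weekly`
#'   (one row per participant with `valid` reflecting the minimum-valid-days
#'   rule).
#' @export
process_events <- function(events, diaries, config = activpal_config()) {
  stopifnot("participant_id" %in% names(events))
  ids <- unique(as.character(events$participant_id))
  daily_rows <- list()
  weekly_rows <- list()
  for (id in ids) {
    ev <- normalize_events(events[events$participant_id == id, , drop = FALSE])
    di <- diaries[as.character(diaries$participant_id) == id, , drop = FALSE]
    di_onset <- as.numeric(di$intended_onset)
    # monitoring days: complete noon-to-noon (configurable hour) windows
    boundary <- config$day_boundary_hour * 3600
    t0 <- floor((min(ev$start) - boundary) / 86400) * 86400 + boundary
    if (t0 < min(ev$start) - 1) t0 <- t0 + 86400
    n_days <- floor((max(ev$end) - t0) / 86400)
    if (n_days < 1) next
    days <- list()
    for (d in seq_len(n_days)) {
      window <- c(t0 + (d - 1) * 86400, t0 + d * 86400)
      hit <- which(di_onset >= window[1] & di_onset < window[2])
      diary_row <- if (length(hit)) di[hit[1], , drop = FALSE] else NULL
      days[[d]] <- process_day(ev, diary_row, window, config)
      days[[d]]$participant_id <- id
      days[[d]]$day <- d
    }
    daily <- do.call(rbind, lapply(days, function(x) {
      data.frame(participant_id = x$participant_id, day = x$day,
                 sleep = x$sleep, sb = x$sb, lpa = x$lpa, mvpa = x$mvpa,
                 nonwear = x$nonwear,
                 wear = if (is.null(x$wear)) 1440 - x$nonwear else x$wear,
                 onset = x$onset, offset = x$offset,
                 onset_source = x$onset_source, offset_source = x$offset_source,
                 valid = x$valid,
                 flags = if (is.null(x$flags)) "" else x$flags,
                 stringsAsFactors = FALSE)
    }))
    wk <- average_week(daily, min_valid_days = config$min_valid_days)
    wk <- cbind(data.frame(participant_id = id, stringsAsFactors = FALSE), wk)
    daily_rows[[id]] <- daily
    weekly_rows[[id]] <- wk
  }
  list(
    daily = do.call(rbind, c(daily_rows, list(make.row.names = FALSE))),
    weekly = do.call(rbind, c(weekly_rows, list(make.row.names = FALSE)))
  )
}
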