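# Independent oracles used across the suite.

hrs <- function(h) h * 3600  # seconds since the (arbitrary) day origin

# Build an event table from parallel vectors of start hours, duration
# minutes, classes and cadences.
make_events <- function(start_h, dur_min, cls, cadence = 0) {
  data.frame(
    start = hrs(start_h),
    duration = dur_min * 60,
    activity_class = cls,
    cadence = cadence
  )
}

# ICC oracle: two-way ANOVA via stats::aov, mean squares read from the
# fitted table -- an independent route to the same decomposition.
icc_oracle_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(
    v = c(x, y),
    id = factor(rep(seq_len(n), 2)),
    occ = factor(rep(1:2, each = n))
  )
  tab <- summary(stats::aov(v ~ id + occ, data = d))[[1]]
  msr <- tab["id", "Mean Sq"]
  msc <- tab["occ", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  list(
    icc_c1 = (msr - mse) / (msr + mse),
    icc_a1 = (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  )
}

# Brute-force second-grid scanner for bursts, candidate window and fusion.
# Works on a 1-second indicator grid -- an independent computational route
# from the package's interval arithmetic.
fusion_oracle <- function(events, diary_onset, diary_wake, grid_start, grid_end,
                          config = activpal_config()) {
  secs <- seq(grid_start, grid_end - 1)
  upright <- logical(length(secs))
  sit <- logical(length(secs))
  for (i in seq_len(nrow(events))) {
    a <- events$start[i] - grid_start + 1
    b <- a + events$duration[i] - 1
    sel <- max(1, a):min(length(secs), b)
    if (events$activity_class[i] == 0) sit[sel] <- TRUE else upright[sel] <- TRUE
  }
  win <- config$burst_window_min * 60
  need <- config$burst_min_upright_min * 60
  cs <- c(0, cumsum(upright))
  nsec <- length(secs)
  qualifying <- logical(nsec)  # seconds lying in a qualifying window
  up_runs <- grid_runs(upright)
  for (r in seq_len(nrow(up_runs))) {
    s <- up_runs$start[r]
    e <- min(nsec, s + win - 1)
    if (cs[e + 1] - cs[s] >= need) qualifying[s:e] <- TRUE
  }
  # upright runs intersecting a qualifying window form bursts; merge runs
  # closer than one window length
  in_burst <- logical(nsec)
  for (r in seq_len(nrow(up_runs))) {
    sel <- up_runs$start[r]:up_runs$end[r]
    if (any(qualifying[sel])) in_burst[sel] <- TRUE
  }
  bruns <- grid_runs(in_burst)
  if (nrow(bruns) > 1) {
    keep <- list(bruns[1, ])
    for (r in 2:nrow(bruns)) {
      last <- keep[[length(keep)]]
      if (bruns$start[r] - last$end <= win) {
        last$end <- bruns$end[r]
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1]] <- bruns[r, ]
      }
    }
    bruns <- do.call(rbind, keep)
  }
  bursts <- data.frame(start = grid_start + bruns$start - 1,
                       end = grid_start + bruns$end)
  if (nrow(bruns) == 0) bursts <- data.frame(start = numeric(0), end = numeric(0))

  # candidate window: exhaustive search over sitting-run pairs
  sruns <- grid_runs(sit)
  best <- NULL; best_span <- -Inf
  budget <- config$interruption_budget_min * 60
  scs <- c(0, cumsum(sit))
  for (i in seq_len(nrow(sruns))) {
    for (j in i:nrow(sruns)) {
      span <- sruns$end[j] - sruns$start[i] + 1
      sit_inside <- scs[sruns$end[j] + 1] - scs[sruns$start[i]]
      if (span - sit_inside <= budget && span > best_span) {
        best_span <- span
        best <- c(sruns$start[i], sruns$end[j])
      }
    }
  }
  if (is.null(best)) return(NULL)
  cand_onset <- grid_start + best[1] - 1
  cand_offset <- grid_start + best[2]

  # onset rule
  if (is.na(diary_onset)) {
    onset <- cand_onset; onset_source <- "event"
  } else {
    w_end <- diary_onset + config$onset_window_min * 60
    hit <- bursts$end > diary_onset & bursts$start <= w_end
    if (!any(hit)) {
      onset <- diary_onset; onset_source <- "diary"
    } else {
      after <- max(bursts$end[hit])
      sit_starts <- grid_start + sruns$start - 1
      ok <- sit_starts[sit_starts >= after - 0.5]
      onset <- if (length(ok)) min(ok) else cand_onset
      onset_source <- "event"
    }
  }

  # offset rule: first post-onset burst with > 1 h sitting before it and
  # no resumed > 1 h sitting after it (before the next burst)
  if (is.na(diary_wake)) {
    offset <- cand_offset; offset_source <- "event"
  } else {
    cand_bursts <- bursts[bursts$start > onset, , drop = FALSE]
    need <- config$offset_min_sit_min * 60
    sit_seconds <- function(a, b) {  # sitting seconds on the grid in [a, b)
      ia <- max(1, a - grid_start + 1)
      ib <- min(nsec, b - grid_start)
      if (ib < ia) 0 else scs[ib + 1] - scs[ia]
    }
    qual <- NULL
    if (nrow(cand_bursts)) {
      for (r in seq_len(nrow(cand_bursts))) {
        from <- if (r > 1) cand_bursts$end[r - 1] else onset
        if (sit_seconds(from, cand_bursts$start[r]) <= need) next
        until <- if (r < nrow(cand_bursts)) cand_bursts$start[r + 1] else grid_end
        if (sit_seconds(cand_bursts$end[r], until) > need) next
        qual <- cand_bursts[r, ]
        break
      }
    }
    if (is.null(qual) || diary_wake < qual$start) {
      offset <- diary_wake; offset_source <- "diary"
    } else {
      sit_ends <- grid_start + sruns$end
      ok <- sit_ends[sit_ends <= qual$start + 0.5]
      offset <- if (length(ok)) max(ok) else cand_offset
      offset_source <- "event"
    }
  }
  list(candidate = list(onset = cand_onset, offset = cand_offset),
       onset = onset, onset_source = onset_source,
       offset = offset, offset_source = offset_source)
}

# runs of TRUE in a logical vector as 1-based [start, end] indices
grid_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# a random plausible night-plus-margins event stream on a 10-s grid,
# for the fusion property test
random_night_stream <- function(seed) {
  set.seed(seed)
  t <- hrs(18)  # evening origin
  rows <- list()
  add <- function(dur_s, cls, cad = 0) {
    rows[[length(rows) + 1]] <<- data.frame(start = t, duration = dur_s,
                                            activity_class = cls, cadence = cad)
    t <<- t + dur_s
  }
  # evening: a few sit/upright alternations
  for (i in seq_len(sample(2:4, 1))) {
    add(sample(6:30, 1) * 60, 0)
    add(sample(2:20, 1) * 60, sample(1:2, 1), 70)
  }
  bed <- t
  # optional in-bed burst
  if (runif(1) < 0.5) {
    add(sample(2:8, 1) * 60, 0)
    add(sample(1:3, 1) * 60, 1)
  }
  # night with 0-2 short interruptions
  night_left <- sample(300:480, 1) * 60
  for (i in seq_len(sample(0:2, 1))) {
    chunk <- round(night_left * runif(1, 0.25, 0.45) / 10) * 10
    add(chunk, 0)
    night_left <- night_left - chunk
    add(sample(c(60, 120, 180), 1), 1)
  }
  add(night_left, 0)
  # morning
  add(sample(5:20, 1) * 60, 1)
  add(sample(5:15, 1) * 60, 2, 80)
  add(sample(10:40, 1) * 60, 0)
  events <- do.call(rbind, rows)
  jit <- function() sample(-15:15, 1) * 60
  list(events = events, bed = bed, end = t,
       diary_onset = bed + jit(),
       diary_wake = events$start[nrow(events)] + jit())
}
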