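test_that("time-in-bed detection merges interruptions within the 15-min budget", {
  # 22:40-03:00 lying, 10-min standing break, 03:10-06:50 lying
  ev <- make_events(c(22 + 40 / 60, 27, 27 + 1 / 6), c(260, 10, 220), c(0, 1, 0))
  w <- detect_time_in_bed(ev)
  expect_equal(w$onset, hrs(22 + 40 / 60))
  expect_equal(w$offset, hrs(27) + 220 * 60 + 600)
  # two 10-min interruptions exceed the budget: only one may be merged and
  # the longest resulting block wins
  ev2 <- make_events(c(0, 3, 1 / 6 + 3, 7 + 1 / 6, 7 + 2 / 6),
                     c(180, 10, 240, 10, 100), c(0, 1, 0, 1, 0))
  w2 <- detect_time_in_bed(ev2)
  expect_equal(w2$onset, hrs(0))           # 180 + 10 + 240 spans 430 min
  expect_equal(w2$offset, hrs(3 + 1 / 6) + 240 * 60)
  # a single uninterrupted event is returned verbatim
  ev3 <- make_events(23, 480, 0)
  expect_equal(detect_time_in_bed(ev3), list(onset = hrs(23), offset = hrs(31)))
  # no sitting/lying at all
  expect_null(detect_time_in_bed(make_events(10, 60, 1)))
})

test_that("burst detection needs a minute of upright time within five minutes", {
  # 2-min standing+stepping burst qualifies
  ev <- make_events(c(23, 23.1, 23.1 + 1 / 60, 23.1 + 2 / 60),
                    c(6, 1, 1, 240), c(0, 1, 2, 0), c(0, 0, 80, 0))
  b <- find_upright_bursts(ev)
  expect_equal(nrow(b), 1)
  expect_equal(b$start, hrs(23.1))
  expect_equal(b$end, hrs(23.1) + 120)
  # a lone 30-s posture flicker does not
  ev2 <- make_events(c(23, 23.2, 23.2 + 0.5 / 60), c(12, 0.5, 240), c(0, 1, 0))
  expect_equal(nrow(find_upright_bursts(ev2)), 0)
  # three 25-s flickers two minutes apart accumulate to a burst
  ev3 <- make_events(c(0, 1, 1 + 25 / 3600, 1 + 2 / 60, 1 + 145 / 3600,
                       1 + 4 / 60, 1 + 265 / 3600),
                     c(60, 25 / 60, 95 / 60, 25 / 60, 95 / 60, 25 / 60, 60),
                     c(0, 1, 0, 1, 0, 1, 0))
  expect_equal(nrow(find_upright_bursts(ev3)), 1)
  # the same flickers an hour apart do not
  ev4 <- make_events(c(0, 1, 1 + 25 / 3600, 2, 2 + 25 / 3600, 3, 3 + 25 / 3600),
                     c(60, 25 / 60, 59 + 35 / 60, 25 / 60, 59 + 35 / 60, 25 / 60, 60),
                     c(0, 1, 0, 1, 0, 1, 0))
  expect_equal(nrow(find_upright_bursts(ev4)), 0)
})

test_that("sleep onset fusion follows the 20-min look-ahead rule", {
  cfg <- activpal_config()
  # no upright events after diary bed time: diary wins
  ev <- make_events(23, 480, 0)
  cand <- detect_time_in_bed(ev)
  r <- fuse_sleep_onset(hrs(23), ev, cand, cfg)
  expect_equal(r, list(time = hrs(23), source = "diary"))
  # burst 5 min after bed time: onset moves to the sitting event after it
  ev2 <- make_events(c(23, 23 + 5 / 60, 23 + 12 / 60), c(5, 7, 468), c(0, 1, 0))
  cand2 <- detect_time_in_bed(ev2)
  r2 <- fuse_sleep_onset(hrs(23), ev2, cand2, cfg)
  expect_equal(r2, list(time = hrs(23) + 12 * 60, source = "event"))
  # burst starting 25 min after bed time falls outside the window
  ev3 <- make_events(c(23, 23 + 25 / 60, 23 + 30 / 60), c(25, 5, 450), c(0, 1, 0))
  r3 <- fuse_sleep_onset(hrs(23), ev3, detect_time_in_bed(ev3), cfg)
  expect_equal(r3, list(time = hrs(23), source = "diary"))
  # missing diary falls back to the candidate window
  r4 <- fuse_sleep_onset(NA, ev, cand, cfg)
  expect_equal(r4, list(time = hrs(23), source = "event"))
})

test_that("sleep offset fusion follows the post-sleep burst rule", {
  cfg <- activpal_config()
  # lying 23:00-06:40, then a burst; diary wake 06:30 precedes it
  ev <- make_events(c(23, 23 + 460 / 60, 23 + 465 / 60),
                    c(460, 5, 30), c(0, 1, 0))
  cand <- detect_time_in_bed(ev)
  on <- hrs(23)
  r <- fuse_sleep_offset(hrs(23) + 450 * 60, ev, cand, on, cfg)
  expect_equal(r, list(time = hrs(23) + 450 * 60, source = "diary"))
  # diary wake after the burst: offset is the end of the last lying event
  r2 <- fuse_sleep_offset(hrs(23) + 480 * 60, ev, cand, on, cfg)
  expect_equal(r2, list(time = hrs(23) + 460 * 60, source = "event"))
  # no burst all morning: diary wins vacuously
  ev3 <- make_events(23, 600, 0)
  r3 <- fuse_sleep_offset(hrs(30), ev3, detect_time_in_bed(ev3), hrs(23), cfg)
  expect_equal(r3, list(time = hrs(30), source = "diary"))
  # missing diary falls back to the candidate offset
  r4 <- fuse_sleep_offset(NA, ev, cand, on, cfg)
  expect_equal(r4, list(time = cand$offset, source = "event"))
})

test_that("a night-time bathroom break does not end the sleep window early", {
  # lying 23:00-02:00, 3-min break, lying to 06:43, rise burst at 06:43
  ev <- make_events(c(23, 26, 26 + 3 / 60, 23 + 463 / 60),
                    c(180, 3, 280, 20), c(0, 1, 0, 1))
  cand <- detect_time_in_bed(ev)
  expect_equal(cand$offset, hrs(23) + 463 * 60)
  r <- fuse_sleep_offset(hrs(23) + 475 * 60, ev, cand, hrs(23))
  expect_equal(r$time, hrs(23) + 463 * 60)  # not 02:00
  expect_equal(r$source, "event")
})

test_that("waking classification splits by posture, cadence and wear", {
  # noon-to-noon day: 480 sleep + 600 sitting + 60 fast stepping + remainder
  day <- c(hrs(12), hrs(36))
  ev <- rbind(
    make_events(12, 300, 0),                 # afternoon sitting
    make_events(17, 60, 2, 115),             # supra-threshold stepping
    make_events(18, 240, 1),                 # standing (LPA)
    make_events(22, 60, 2, 80),              # slow stepping (LPA)
    make_events(23, 480, 0),                 # night
    make_events(31, 300, 0)                  # morning sitting
  )
  parts <- classify_waking(ev, hrs(23), hrs(31), day)
  expect_equal(parts$sleep, 480)
  expect_equal(parts$sb, 600)
  expect_equal(parts$mvpa, 60)
  expect_equal(parts$lpa, 300)
  expect_equal(parts$nonwear, 0)
  expect_equal(parts$sb + parts$lpa + parts$mvpa + parts$nonwear + parts$sleep, 1440)
  # removing an hour of standing opens a non-wear gap, preserving closure
  p1 <- classify_waking(ev[-3, ], hrs(23), hrs(31), day)
  expect_equal(p1$nonwear, 240)
  expect_equal(p1$lpa, 60)
  expect_equal(p1$sb + p1$lpa + p1$mvpa + p1$nonwear + p1$sleep, 1440)
  # an event straddling the sleep boundary is split there: the 22:00-08:00
  # sitting event contributes one waking hour before 23:00 and one after 07:00
  ev2 <- rbind(make_events(12, 600, 0), make_events(22, 600, 0))
  p2 <- classify_waking(ev2, hrs(23), hrs(31), day)
  expect_equal(p2$sb, 600 + 60 + 60)
})

test_that("nap transfer moves minutes from SB to sleep and flags overshoot", {
  s <- list(sleep = 450, sb = 600, lpa = 300, mvpa = 60)
  a <- adjust_naps(s, 30)
  expect_equal(a$sleep, 480)
  expect_equal(a$sb, 570)
  expect_false(a$nap_overshoot)
  expect_equal(adjust_naps(s, 0)$sleep, 450)
  b <- adjust_naps(list(sleep = 450, sb = 20, lpa = 900, mvpa = 60), 30)
  expect_equal(b$sb, 0)
  expect_equal(b$sleep, 470)
  expect_true(b$nap_overshoot)
  expect_error(adjust_naps(s, -5), "non-negative")
})

test_that("wear-time validity uses the strict 20-h rule", {
  expect_true(account_nonwear(0)$valid)
  expect_false(account_nonwear(300)$valid)   # a five-hour gap
  expect_true(account_nonwear(210)$valid)    # 3.5-h gap leaves 20.5 h wear
  expect_false(account_nonwear(240)$valid)   # exactly 20 h is not "more than"
})

test_that("non-wear reallocation scales waking behaviours proportionally", {
  s <- list(sleep = 480, sb = 480, lpa = 300, mvpa = 60, nonwear = 120, valid = TRUE)
  r <- reallocate_nonwear(s)
  expect_equal(r$sb, 480 * 960 / 840)
  expect_equal(r$lpa, 300 * 960 / 840)
  expect_equal(r$mvpa, 60 * 960 / 840)
  expect_equal(r$sleep, 480)
  expect_equal(r$sleep + r$sb + r$lpa + r$mvpa, 1440, tolerance = 1e-9)
  # identity and zero preservation
  s0 <- list(sleep = 480, sb = 600, lpa = 360, mvpa = 0, nonwear = 0, valid = TRUE)
  expect_identical(reallocate_nonwear(s0), s0)
  s1 <- list(sleep = 480, sb = 840, lpa = 60, mvpa = 0, nonwear = 60, valid = TRUE)
  expect_equal(reallocate_nonwear(s1)$mvpa, 0)
  # no waking time at all cannot be reallocated
  s2 <- list(sleep = 1380, sb = 0, lpa = 0, mvpa = 0, nonwear = 60, valid = TRUE)
  expect_false(reallocate_nonwear(s2)$valid)
})

test_that("weekly averaging uses valid days only and enforces the 5-day rule", {
  d <- data.frame(sleep = c(420, 440, 460, 480, 500, 400, 999),
                  sb = 600, lpa = 360, mvpa = 60,
                  valid = c(rep(TRUE, 5), FALSE, FALSE))
  w <- average_week(d)
  expect_true(w$valid)
  expect_equal(w$sleep, 460)
  expect_equal(w$n_valid_days, 5)
  d$valid[5] <- FALSE
  expect_false(average_week(d)$valid)
  # identical valid days average to themselves
  d7 <- data.frame(sleep = 450, sb = 600, lpa = 330, mvpa = 60, valid = TRUE)[rep(1, 7), ]
  expect_equal(average_week(d7)$sleep, 450)
  expect_error(average_week(d7[0, ]), "no daily")
})

test_that("fusion matches the brute-force grid scanner on random streams", {
  cfg <- activpal_config()
  for (seed in 1:30) {
    st <- random_night_stream(seed)
    oracle <- fusion_oracle(st$events, st$diary_onset, st$diary_wake,
                            hrs(18), st$end, cfg)
    cand <- detect_time_in_bed(st$events, config = cfg)
    expect_equal(cand$onset, oracle$candidate$onset, info = paste("seed", seed))
    expect_equal(cand$offset, oracle$candidate$offset, info = paste("seed", seed))
    on <- fuse_sleep_onset(st$diary_onset, st$events, cand, cfg)
    expect_equal(on$time, oracle$onset, info = paste("seed", seed))
    expect_equal(on$source, oracle$onset_source, info = paste("seed", seed))
    off <- fuse_sleep_offset(st$diary_wake, st$events, cand, on$time, cfg)
    expect_equal(off$time, oracle$offset, info = paste("seed", seed))
    expect_equal(off$source, oracle$offset_source, info = paste("seed", seed))
  }
})

test_that("overlapping events are rejected", {
  ev <- make_events(c(10, 10.5), c(60, 30), c(0, 1))
  expect_error(detect_time_in_bed(ev), "overlap")
})
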