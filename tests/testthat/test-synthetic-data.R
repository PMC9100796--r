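# a convenient noise-free configuration: between-subject variation only
quiet_config <- function(...) {
  args <- list(
    test_retest_error_sd = c(sleep = 0, sb = 0, mvpa = 0),
    device_error_sd = c(sleep = 0, sb = 0, mvpa = 0),
    device_bias = c(sleep = 0, sb = 0, mvpa = 0),
    device_attenuation = c(sleep = 1, sb = 1, mvpa = 1),
    construct_error_sd = c(sleep = 0, sb = 0, mvpa = 0),
    diary_jitter_sd = 0, burst_probability = 0,
    nonwear_rate = 0, nonwear_gap_probability = 0,
    p_missing_occasion2 = 0, p_noncompliant = 0
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_participants = 6, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(generate_dabq_table(c1, 1, cfg), generate_dabq_table(c2, 1, cfg))
  s1 <- generate_event_stream(c1[3, ], cfg)
  s2 <- generate_event_stream(c2[3, ], cfg)
  expect_identical(s1, s2)
  # different seeds give different cohorts
  expect_false(identical(c1, generate_cohort(cohort_config(n_participants = 6, seed = 124))))
})

test_that("zero between-subject spread degenerates to the population mean", {
  cfg <- quiet_config(n_participants = 5, seed = 1,
                      between_sd = c(sleep = 0, sb = 0, mvpa = 0))
  co <- generate_cohort(cfg)
  expect_equal(co$sleep, rep(443, 5))
  expect_equal(co$sb, rep(547, 5))
  expect_equal(co$mvpa, rep(31, 5))
  expect_equal(co$lpa, rep(419, 5))
})

test_that("latent compositions close to 1440 and stay positive", {
  co <- generate_cohort(cohort_config(n_participants = 400, seed = 5))
  expect_true(all(abs(co$sleep + co$sb + co$lpa + co$mvpa - 1440) < 1e-9))
  expect_true(all(co$sleep > 0 & co$sb > 0 & co$lpa > 0 & co$mvpa > 0))
  expect_error(generate_cohort(cohort_config(n_participants = 1)), "at least 2")
})

test_that("cohort means converge to the configured population means", {
  co <- generate_cohort(cohort_config(n_participants = 10000, seed = 99))
  expect_equal(mean(co$sleep), 443, tolerance = 2 / 443)
  expect_equal(mean(co$sb), 547, tolerance = 5.5 / 547)
  expect_equal(mean(co$mvpa), 31, tolerance = 1.2 / 31)
  expect_equal(mean(co$lpa), 419, tolerance = 6 / 419)
})

test_that("zero test-retest noise makes the two occasions score identically", {
  cfg <- quiet_config(n_participants = 6, seed = 11)
  co <- generate_cohort(cfg)
  s1 <- score_dabq(generate_dabq_table(co, 1, cfg))
  s2 <- score_dabq(generate_dabq_table(co, 2, cfg))
  expect_equal(s1[behaviour_names()], s2[behaviour_names()], tolerance = 1e-12)
})

test_that("noise-free questionnaire responses score back to the latent truth", {
  cfg <- quiet_config(n_participants = 20, seed = 21)
  co <- generate_cohort(cfg)
  sc <- score_dabq(generate_dabq_table(co, 1, cfg))
  expect_true(all(sc$valid))
  for (b in behaviour_names()) {
    expect_lt(max(abs(sc[[b]] - co[[b]])), 1)
  }
  # responses are internally consistent: occupational MVPA fits inside the
  # reported workplace hours
  r <- generate_dabq_table(co, 1, cfg)
  span <- (parse_hhmm(r$work_departure) - parse_hhmm(r$work_arrival)) %% 1440
  expect_true(all(r$occupational_mvpa_duration <= pmax(span, 0) |
                    r$occupational_mvpa_flag == "no"))
})

test_that("noise-free event streams are recovered exactly by processing", {
  cfg <- quiet_config(n_participants = 4, seed = 31)
  co <- generate_cohort(cfg)
  for (i in seq_len(nrow(co))) {
    s <- generate_event_stream(co[i, ], cfg, n_days = 7)
    p <- process_events(s$events, s$diary)
    m <- merge(p$daily, s$truth, by = "day", suffixes = c(".est", ".tru"))
    for (b in behaviour_names()) {
      expect_lt(max(abs(m[[paste0(b, ".est")]] - m[[paste0(b, ".tru")]])), 1)
    }
    expect_true(p$weekly$valid)
    expect_equal(p$weekly$n_valid_days, 7)
    # weekly estimate recovers the participant's latent composition
    for (b in behaviour_names()) {
      expect_lt(abs(p$weekly[[b]] - co[[b]][i]), 1)
    }
  }
})

test_that("event streams tile each day except explicit non-wear gaps", {
  cfg <- cohort_config(n_participants = 2, seed = 41)
  co <- generate_cohort(cfg)
  s <- generate_event_stream(co[1, ], cfg, n_days = 7)
  ev <- s$events
  start <- as.numeric(ev$start)
  end <- start + ev$duration
  o <- order(start)
  # non-overlapping and time-ordered
  expect_true(all(start[o][-1] >= end[o][-length(end)] - 1e-9))
  # covered time + declared non-wear = 7 full days
  covered <- sum(ev$duration)
  expect_equal(covered / 60 + sum(s$truth$nonwear), 7 * 1440, tolerance = 0.1)
})

test_that("long non-wear gaps invalidate the day downstream", {
  cfg <- cohort_config(n_participants = 3, seed = 51, nonwear_rate = 4,
                       nonwear_gap_probability = 0.8)
  co <- generate_cohort(cfg)
  s <- generate_event_stream(co[2, ], cfg, n_days = 7)
  p <- process_events(s$events, s$diary)
  m <- merge(p$daily, s$truth, by = "day")
  expect_gt(sum(m$nonwear.y > 240), 0)  # the config produced some long gaps
  expect_equal(m$valid, m$nonwear.y < 240)
  expect_equal(m$nonwear.x, m$nonwear.y, tolerance = 0.51)
})

test_that("an upright burst after bedtime moves the fused onset off the diary", {
  cfg <- quiet_config(n_participants = 3, seed = 61, burst_probability = 1)
  co <- generate_cohort(cfg)
  s <- generate_event_stream(co[1, ], cfg, n_days = 7)
  p <- process_events(s$events, s$diary)
  shift <- (p$daily$onset - as.numeric(s$diary$intended_onset)) / 60
  expect_true(all(p$daily$onset_source == "event"))
  # in-bed sitting (3-8 min) plus the 2-min burst separates diary and onset
  expect_true(all(shift >= 5 & shift <= 10))
  # sleep is still recovered because truth starts after the burst
  m <- merge(p$daily, s$truth, by = "day", suffixes = c(".est", ".tru"))
  expect_lt(max(abs(m$sleep.est - m$sleep.tru)), 1)
})

test_that("the implied test-retest ICC tracks the variance-ratio target", {
  # sigma_b^2 / (sigma_b^2 + sigma_e^2) = 0.8 for sleep
  sd_b <- 50; sd_e <- 25
  cfg <- quiet_config(n_participants = 250, seed = 71,
                      between_sd = c(sleep = sd_b, sb = 150, mvpa = 28),
                      test_retest_error_sd = c(sleep = sd_e, sb = 0, mvpa = 0))
  co <- generate_cohort(cfg)
  s1 <- score_dabq(generate_dabq_table(co, 1, cfg))
  s2 <- score_dabq(generate_dabq_table(co, 2, cfg))
  icc <- icc_two_way_mixed(s1$sleep, s2$sleep)$icc_c1
  truth <- sd_b^2 / (sd_b^2 + sd_e^2)
  expect_equal(icc, truth, tolerance = 0.05 / truth)
})
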