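#' Test-retest reliability report
#'
#' Compares the scored compositions from two questionnaire occasions.
#' Participants missing a valid record on either occasion are dropped (and
#' counted). Per behaviour the report holds occasion means and SDs, the
#' two-way mixed ICCs for absolute agreement and consistency with 95% CIs,
#' the bootstrap Spearman correlation, and the mean test-retest difference
#' with its t-based CI.
#'
#' @param scored1,scored2 composition tables from [score_dabq()] (occasion
#'   1 and 2).
#' @param B bootstrap resamples for the Spearman interval.
#' @param seed RNG seed for the bootstrap.
#' @return list with `table` (one row per behaviour), `n_pairs`,
#'   `n_dropped`.
#' @export
run_reliability <- function(scored1, scored2, B = 2000, seed = 1L) {
  s1 <- scored1[scored1$valid, , drop = FALSE]
  s2 <- scored2[scored2$valid, , drop = FALSE]
  ids <- intersect(s1$participant_id, s2$participant_id)
  n_all <- length(union(scored1$participant_id, scored2$participant_id))
  if (length(ids) < 2) stop("fewer than 2 complete pairs")
  a <- s1[match(ids, s1$participant_id), ]
  b <- s2[match(ids, s2$participant_id), ]
  rows <- lapply(behaviour_names(), function(bh) {
    x <- a[[bh]]; y <- b[[bh]]
    bat <- agreement_battery(x, y, B = B, seed = seed)
    data.frame(
      behaviour = bh,
      mean1 = mean(x), sd1 = stats::sd(x),
      mean2 = mean(y), sd2 = stats::sd(y),
      icc_a1 = bat$icc$icc_a1,
      icc_a1_lcl = bat$icc$icc_a1_ci[1], icc_a1_ucl = bat$icc$icc_a1_ci[2],
      icc_c1 = bat$icc$icc_c1,
      icc_c1_lcl = bat$icc$icc_c1_ci[1], icc_c1_ucl = bat$icc$icc_c1_ci[2],
      rho = bat$spearman$rho,
      rho_lcl = bat$spearman$ci[1], rho_ucl = bat$spearman$ci[2],
      mean_diff = bat$bland_altman$mean_diff,
      mean_diff_lcl = bat$bland_altman$mean_diff_ci[1],
      mean_diff_ucl = bat$bland_altman$mean_diff_ci[2],
      n = bat$n,
      stringsAsFactors = FALSE
    )
  })
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       n_pairs = length(ids), n_dropped = n_all - length(ids))
}

#' Convergent validity report with Bland-Altman outputs
#'
#' Compares scored questionnaire compositions (occasion 2 by convention)
#' against device-derived weekly compositions restricted to participants
#' meeting the valid-days rule. Per behaviour: ICCs, Spearman, mean
#' difference (questionnaire minus device) with CI, limits of agreement
#' with CIs, and proportional bias. Also emits the per-participant
#' (mean, difference) pairs used for Bland-Altman plotting.
#'
#' @param scored questionnaire composition table from [score_dabq()].
#' @param device weekly device table from [process_events()].
#' @param B,seed bootstrap settings.
#' @return list with `table`, `ba_pairs`, `n_pairs`, `n_dropped`.
#' @export
run_validity <- function(scored, device, B = 2000, seed = 1L) {
  s <- scored[scored$valid, , drop = FALSE]
  dv <- device[device$valid, , drop = FALSE]
  ids <- intersect(s$participant_id, dv$participant_id)
  n_all <- length(union(scored$participant_id, device$participant_id))
  if (length(ids) < 2) stop("fewer than 2 complete pairs")
  a <- s[match(ids, s$participant_id), ]
  b <- dv[match(ids, dv$participant_id), ]
  rows <- list(); pairs <- list()
  for (bh in behaviour_names()) {
    x <- a[[bh]]; y <- b[[bh]]
    bat <- agreement_battery(x, y, B = B, seed = seed)
    ba <- bat$bland_altman
    rows[[bh]] <- data.frame(
      behaviour = bh,
      mean1 = mean(x), sd1 = stats::sd(x),
      mean2 = mean(y), sd2 = stats::sd(y),
      icc_a1 = bat$icc$icc_a1,
      icc_a1_lcl = bat$icc$icc_a1_ci[1], icc_a1_ucl = bat$icc$icc_a1_ci[2],
      icc_c1 = bat$icc$icc_c1,
      icc_c1_lcl = bat$icc$icc_c1_ci[1], icc_c1_ucl = bat$icc$icc_c1_ci[2],
      rho = bat$spearman$rho,
      rho_lcl = bat$spearman$ci[1], rho_ucl = bat$spearman$ci[2],
      mean_diff = ba$mean_diff,
      mean_diff_lcl = ba$mean_diff_ci[1], mean_diff_ucl = ba$mean_diff_ci[2],
      sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower,
      loa_lower_lcl = ba$loa_lower_ci[1], loa_lower_ucl = ba$loa_lower_ci[2],
      loa_upper = ba$loa_upper,
      loa_upper_lcl = ba$loa_upper_ci[1], loa_upper_ucl = ba$loa_upper_ci[2],
      prop_bias_beta = ba$prop_bias_beta, prop_bias_p = ba$prop_bias_p,
      n = bat$n,
      stringsAsFactors = FALSE
    )
    pairs[[bh]] <- data.frame(
      behaviour = bh, participant_id = ids,
      mean = ba$means, diff = ba$diffs,
      stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ba_pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
       n_pairs = length(ids), n_dropped = n_all - length(ids))
}

#' Run the full study emulation
#'
#' Simulates a cohort, scores both questionnaire occasions, processes the
#' device event streams, and produces the reliability and validity reports,
#' with filter accounting mirroring a validation study's participant flow
#' (completed both occasions; enough valid device days).
#'
#' @param config settings from [cohort_config()]; its seed controls every
#'   stochastic step.
#' @param n_days device monitoring days.
#' @param B bootstrap resamples.
#' @param proc_config device-processing settings from [activpal_config()].
#' @return list with `study` (raw simulated tables), `scored1`, `scored2`,
#'   `device`, `reliability`, `validity`, and a `counts` list.
#' @export
run_all <- function(config = cohort_config(), n_days = 7, B = 2000,
                    proc_config = activpal_config()) {
  study <- generate_study(config, n_days = n_days)
  scored1 <- score_dabq(study$dabq1)
  scored2 <- score_dabq(study$dabq2)
  proc <- process_events(study$events, study$diaries, proc_config)
  seed_stats <- derive_seed(config$seed, 9)
  rel <- run_reliability(scored1, scored2, B = B, seed = seed_stats)
  val <- run_validity(scored2, proc$weekly, B = B, seed = seed_stats)
  counts <- list(
    n_cohort = nrow(study$cohort),
    n_occasion1 = nrow(scored1),
    n_occasion2 = nrow(scored2),
    n_reliability = rel$n_pairs,
    n_device_valid = sum(proc$weekly$valid),
    n_validity = val$n_pairs
  )
  list(study = study, scored1 = scored1, scored2 = scored2,
       daily = proc$daily, device = proc$weekly,
       reliability = rel, validity = val, counts = counts)
}
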