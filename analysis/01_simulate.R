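#!/usr/bin/env Rscript

# Simulate the validation study: a cohort of working adults with known
# latent 24-h compositions, two questionnaire administrations a week apart,
# and seven days of device events with daily sleep diaries. Writes the
# measurement files (and, separately, the ground truth) under
# results/study/.

suppressPackageStartupMessages(library(timeuse24))

seed <- 20260901L
config <- cohort_config(seed = seed)
study <- generate_study(config, n_days = 7)
write_study(study, "results/study")

message("cohort: ", nrow(study$cohort), " participants (seed ", seed, ")")
message("questionnaire occasion 1: ", nrow(study$dabq1), " responses")
message("questionnaire occasion 2: ", nrow(study$dabq2),
        " responses (", nrow(study$dabq1) - nrow(study$dabq2), " non-responders)")
message("device events: ", nrow(study$events), " rows across ",
        length(unique(study$events$participant_id)), " participants")
message("written to results/study/")
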