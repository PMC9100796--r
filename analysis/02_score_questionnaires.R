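#!/usr/bin/env Rscript

# Score both questionnaire occasions into closed 24-h compositions
# (sleep / SB / LPA / MVPA, min/day) and report how many records were
# flagged invalid (over-reported days with negative LPA remainders).

suppressPackageStartupMessages(library(timeuse24))

study <- read_study("results/study")
for (occ in 1:2) {
  responses <- study[[paste0("dabq", occ)]]
  scored <- score_dabq(responses)
  write_study_table(scored, sprintf("results/scored_occasion%d.tsv", occ))
  message("occasion ", occ, ": scored ", nrow(scored), " records, ",
          sum(!scored$valid), " invalid; mean composition ",
          paste(sprintf("%s %.0f", names(scored)[3:6],
                        colMeans(scored[scored$valid, 3:6])), collapse = ", "),
          " min/day")
}
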