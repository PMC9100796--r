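#!/usr/bin/env Rscript

# Test-retest reliability of the questionnaire: per behaviour, two-way
# mixed ICCs (absolute agreement and consistency) with 95% CIs, bootstrap
# Spearman correlations, and mean test-retest differences.

suppressPackageStartupMessages(library(timeuse24))

s1 <- read_study_table("results/scored_occasion1.tsv")
s2 <- read_study_table("results/scored_occasion2.tsv")
rel <- run_reliability(s1, s2, B = 2000, seed = 20260901L)
write_study_table(rel$table, "results/reliability.tsv")

message(rel$n_pairs, " complete pairs (", rel$n_dropped, " dropped)")
for (i in seq_len(nrow(rel$table))) {
  r <- rel$table[i, ]
  message(sprintf(
    "%-5s ICC[A,1] %.2f (%.2f, %.2f)  ICC[C,1] %.2f (%.2f, %.2f)  rho %.2f  mean diff %+.1f min/day",
    r$behaviour, r$icc_a1, r$icc_a1_lcl, r$icc_a1_ucl,
    r$icc_c1, r$icc_c1_lcl, r$icc_c1_ucl, r$rho, r$mean_diff))
}
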