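#!/usr/bin/env Rscript

# Convergent validity of the questionnaire against the device: ICCs,
# Spearman correlations, Bland-Altman mean differences and limits of
# agreement with CIs, and proportional bias. Also writes the plot-ready
# per-participant (mean, difference) pairs.

suppressPackageStartupMessages(library(timeuse24))

s2 <- read_study_table("results/scored_occasion2.tsv")
device <- read_study_table("results/device_weekly.tsv")
val <- run_validity(s2, device, B = 2000, seed = 20260901L)
write_study_table(val$table, "results/validity.tsv")
write_study_table(val$ba_pairs, "results/bland_altman_pairs.tsv")

message(val$n_pairs, " questionnaire/device pairs analysed")
for (i in seq_len(nrow(val$table))) {
  r <- val$table[i, ]
  message(sprintf(
    "%-5s ICC[A,1] %.2f  rho %.2f  mean diff %+.1f (%.1f, %.1f)  LoA (%.1f, %.1f)  beta %.2f",
    r$behaviour, r$icc_a1, r$rho, r$mean_diff, r$mean_diff_lcl, r$mean_diff_ucl,
    r$loa_lower, r$loa_upper, r$prop_bias_beta))
}
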