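#!/usr/bin/env Rscript

# Process the device event streams: candidate time-in-bed detection,
# diary fusion of sleep onset/offset, cadence-based waking classification,
# nap transfer, non-wear accounting with proportional reallocation, and
# valid-day weekly averaging.

suppressPackageStartupMessages(library(timeuse24))

study <- read_study("results/study")
proc <- process_events(study$events, study$diaries, activpal_config())
write_study_table(proc$daily, "results/device_daily.tsv")
write_study_table(proc$weekly, "results/device_weekly.tsv")

message("processed ", nrow(proc$daily), " participant-days; ",
        sum(proc$daily$valid), " valid (>20 h wear)")
message("onset source: ", sum(proc$daily$onset_source == "diary", na.rm = TRUE),
        " diary / ", sum(proc$daily$onset_source == "event", na.rm = TRUE), " event; ",
        "offset source: ", sum(proc$daily$offset_source == "diary", na.rm = TRUE),
        " diary / ", sum(proc$daily$offset_source == "event", na.rm = TRUE), " event")
message(sum(proc$weekly$valid), " of ", nrow(proc$weekly),
        " participants reached 5 valid days")
ok <- proc$weekly[proc$weekly$valid, ]
message("device mean composition: ",
        paste(sprintf("%s %.0f", c("sleep", "sb", "lpa", "mvpa"),
                      colMeans(ok[, c("sleep", "sb", "lpa", "mvpa")])),
              collapse = ", "), " min/day")
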