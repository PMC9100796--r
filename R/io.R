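#' Write and read the study's delimited text formats
#'
#' All tables travel as tab-separated text with a header row. Event and
#' diary timestamps are ISO-8601 in UTC; activity classes are coded
#' 0 = sitting/lying, 1 = standing, 2 = stepping.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_study_table()` returns `path` invisibly;
#'   `read_study_table()` returns a data.frame.
#' @export
write_study_table <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (inherits(x[[nm]], "POSIXct")) {
      x[[nm]] <- format(x[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    }
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @param datetime_cols columns to parse as ISO-8601 UTC timestamps.
#' @export
read_study_table <- function(path, datetime_cols = character(0)) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (nm in intersect(datetime_cols, names(x))) {
    x[[nm]] <- as.POSIXct(x[[nm]], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  x
}

#' Write a simulated study to a directory of delimited files
#'
#' Ground truth is written separately from the measurement files so the
#' processing pipeline never reads it.
#'
#' @param study list from [generate_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_study_table(study$dabq1, file.path(dir, "dabq_occasion1.tsv"))
  write_study_table(study$dabq2, file.path(dir, "dabq_occasion2.tsv"))
  write_study_table(study$events, file.path(dir, "events.tsv"))
  write_study_table(study$diaries, file.path(dir, "diaries.tsv"))
  write_study_table(study$truth, file.path(dir, "ground_truth.tsv"))
  write_study_table(study$cohort, file.path(dir, "cohort_truth.tsv"))
  invisible(dir)
}

#' Read a simulated study back from a directory
#'
#' @param dir directory written by [write_study()].
#' @return list with `dabq1`, `dabq2`, `events`, `diaries` (measurement
#'   files only).
#' @export
read_study <- function(dir) {
  list(
    dabq1 = read_study_table(file.path(dir, "dabq_occasion1.tsv")),
    dabq2 = read_study_table(file.path(dir, "dabq_occasion2.tsv")),
    events = read_study_table(file.path(dir, "events.tsv"),
                              datetime_cols = "start"),
    diaries = read_study_table(file.path(dir, "diaries.tsv"),
                               datetime_cols = c("intended_onset", "wake_time"))
  )
}
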