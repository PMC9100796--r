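#' Parse "hh:mm" clock strings to minutes since midnight
#'
#' @param x character vector of clock times such as "23:05".
#' @return numeric vector of minutes since midnight in \[0, 1440).
#' @export
parse_hhmm <- function(x) {
  stopifnot(is.character(x) | is.factor(x))
  x <- as.character(x)
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x) | is.na(x)
  if (!all(ok)) stop("malformed clock time(s): ", paste(x[!ok], collapse = ", "))
  h <- as.numeric(sub(":.*", "", x))
  m <- as.numeric(sub(".*:", "", x))
  h * 60 + m
}

#' Format minutes since midnight as "hh:mm"
#'
#' @param m numeric vector of minutes since midnight; reduced modulo 1440.
#' @return character vector of clock strings.
#' @export
format_hhmm <- function(m) {
  m <- round(m) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# Clock span bed -> rise with overnight wrap: rise at or before bed means
# next-day rise, so equal times give a full 24 h in bed.
clock_span_sleep <- function(bed_min, rise_min) {
  span <- rise_min - bed_min
  ifelse(span <= 0, span + 1440, span)
}

# Workplace span arrival -> departure: equal times mean no time at work;
# departure before arrival wraps overnight (shift work).
clock_span_work <- function(arrival_min, departure_min) {
  (departure_min - arrival_min) %% 1440
}
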