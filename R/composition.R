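#' Construct a 24-h time-use composition
#'
#' A time-use composition holds the daily minutes spent in the four 24-h
#' movement behaviours -- sleep, sedentary behaviour (SB), light physical
#' activity (LPA) and moderate-to-vigorous physical activity (MVPA) -- which
#' are co-dependent and close to 1440 min/day.
#'
#' @param sleep,sb,lpa,mvpa minutes per day; numeric vectors of equal length.
#' @param valid logical; whether the row satisfies closure and non-negativity.
#'   Defaults to a check of both conditions.
#' @return a data.frame with columns `sleep`, `sb`, `lpa`, `mvpa`, `valid`.
#' @export
time_use_composition <- function(sleep, sb, lpa, mvpa, valid = NULL) {
  n <- length(sleep)
  stopifnot(length(sb) == n, length(lpa) == n, length(mvpa) == n)
  if (is.null(valid)) {
    total <- sleep + sb + lpa + mvpa
    valid <- abs(total - 1440) < 1e-6 &
      sleep >= 0 & sb >= 0 & lpa >= 0 & mvpa >= 0
    valid[is.na(valid)] <- FALSE
  }
  data.frame(sleep = sleep, sb = sb, lpa = lpa, mvpa = mvpa, valid = valid)
}

#' Check closure of a composition table
#'
#' @param comp data.frame with columns sleep, sb, lpa, mvpa.
#' @param tol absolute tolerance on the 1440-min daily total.
#' @return logical vector, one element per row.
#' @export
is_closed_composition <- function(comp, tol = 1e-6) {
  abs(comp$sleep + comp$sb + comp$lpa + comp$mvpa - 1440) < tol
}

# Behaviour names in fixed reporting order.
behaviour_names <- function() c("sleep", "sb", "lpa", "mvpa")
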