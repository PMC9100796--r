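#' Two-way mixed single-measure intraclass correlations
#'
#' Computes ICC(A,1) (absolute agreement) and ICC(C,1) (consistency) for a
#' participants-by-occasions table with k = 2 columns, from the two-way
#' ANOVA decomposition, together with 95% confidence intervals.
#'
#' Definitions and confidence intervals follow the single-measure two-way
#' conventions of McGraw & Wong (1996): with MS_R, MS_C, MS_E the row
#' (participant), column (occasion/method) and error mean squares,
#' ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E) and
#' ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)).
#' The ICC(C,1) interval is F-based on MS_R/MS_E with (n-1, (n-1)(k-1))
#' degrees of freedom; the ICC(A,1) interval uses the Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param x,y paired measurements (occasion/method 1 and 2); equal-length
#'   numeric vectors with no missing values.
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @return list with elements `icc_a1`, `icc_a1_ci`, `icc_c1`, `icc_c1_ci`
#'   (each CI a length-2 numeric), the mean squares, and `n`.
#' @export
icc_two_way_mixed <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 2) stop("at least 2 paired observations are required")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  if (msr <= 0 && msc <= 0 && mse <= 0) {
    stop("zero variance in rows and columns: ICC undefined")
  }

  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  qf_hi <- function(df1, df2) stats::qf(1 - alpha / 2, df1, df2)

  # Consistency CI: F = MS_R/MS_E with (n-1, (n-1)(k-1)) df.
  if (mse <= .Machine$double.eps * msr) {
    ci_c <- c(1, 1)
  } else {
    fobs <- msr / mse
    fl <- fobs / qf_hi(n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf_hi((n - 1) * (k - 1), n - 1)
    ci_c <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }

  # Absolute-agreement CI (McGraw & Wong 1996, Table 7).
  if (mse <= .Machine$double.eps * msr && msc <= .Machine$double.eps * msr) {
    ci_a <- c(1, 1)
  } else {
    a <- (k * icc_a) / (n * (1 - icc_a))
    b <- 1 + (k * icc_a * (n - 1)) / (n * (1 - icc_a))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fstar <- qf_hi(n - 1, v)
    fdstar <- qf_hi(v, n - 1)
    lower <- n * (msr - fstar * mse) /
      (fstar * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fdstar * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fdstar * msr)
    ci_a <- c(lower, upper)
  }

  list(
    icc_a1 = icc_a, icc_a1_ci = ci_a,
    icc_c1 = icc_c, icc_c1_ci = ci_c,
    ms_rows = msr, ms_cols = msc, ms_error = mse,
    n = n, k = k
  )
}

#' Spearman rank correlation with bootstrap confidence interval
#'
#' Point estimate by the average-rank (mid-rank) Spearman formula; interval
#' by paired case resampling with a percentile interval. Resamples in which
#' either vector is constant contribute no correlation and are dropped.
#'
#' @param x,y paired measurements, length >= 3, no missing values.
#' @param B number of bootstrap resamples.
#' @param seed integer RNG seed; required so intervals are reproducible.
#' @param conf confidence level.
#' @return list with `rho`, `ci` (length-2), `n`, `B_used`.
#' @export
spearman_bootstrap <- function(x, y, B = 2000, seed, conf = 0.95) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for an all-tied vector")
  }
  if (missing(seed)) stop("a seed is required for the bootstrap interval")
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  rho_b <- vapply(seq_len(B), function(b) {
    i <- idx[b, ]
    xb <- x[i]; yb <- y[i]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
    stats::cor(xb, yb, method = "spearman")
  }, numeric(1))
  rho_b <- rho_b[!is.na(rho_b)]
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(rho = rho, ci = unname(stats::quantile(rho_b, probs)), n = n,
       B_used = length(rho_b))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `x - y`. The mean difference carries a t-based confidence
#' interval; limits of agreement are mean +/- 1.96 SD of the differences with
#' intervals based on SE(LoA) = SD * sqrt(3/n) (Bland & Altman 1986).
#' Proportional bias is the OLS slope of the differences on the pair means
#' `(x + y) / 2`, with its t-test p-value.
#'
#' @param x,y paired measurements (e.g. questionnaire and device estimates).
#' @param conf confidence level for all intervals.
#' @return list with `mean_diff`, `mean_diff_ci`, `sd_diff`, `loa_lower`,
#'   `loa_lower_ci`, `loa_upper`, `loa_upper_ci`, `prop_bias_beta`,
#'   `prop_bias_p`, `n`, and the per-pair `means`/`diffs` used for plotting.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  d <- x - y
  a <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  se_md <- sdd / sqrt(n)
  loa_l <- md - 1.96 * sdd
  loa_u <- md + 1.96 * sdd
  se_loa <- sdd * sqrt(3 / n)
  if (stats::var(a) > 0 && sdd > 0) {
    # degenerate inputs (exactly collinear d and a) trip an lm precision
    # warning that is expected here
    fit <- suppressWarnings(stats::summary.lm(stats::lm(d ~ a)))
    beta <- fit$coefficients["a", "Estimate"]
    beta_p <- fit$coefficients["a", "Pr(>|t|)"]
  } else {
    beta <- 0
    beta_p <- NA_real_
  }
  list(
    mean_diff = md, mean_diff_ci = c(md - tq * se_md, md + tq * se_md),
    sd_diff = sdd,
    loa_lower = loa_l, loa_lower_ci = c(loa_l - tq * se_loa, loa_l + tq * se_loa),
    loa_upper = loa_u, loa_upper_ci = c(loa_u - tq * se_loa, loa_u + tq * se_loa),
    prop_bias_beta = beta, prop_bias_p = beta_p,
    n = n, means = a, diffs = d
  )
}

#' Bonett sample size for an ICC confidence interval of target width
#'
#' Closed-form planning formula (Bonett 2002) for the number of participants
#' needed so that the `1 - alpha` confidence interval for an anticipated
#' intraclass correlation `rho0`, measured `k` times, has total width `w`
#' (i.e. half-width `w / 2`):
#' n = ceiling( 8 z^2 (1-rho0)^2 (1+(k-1) rho0)^2 / (k (k-1) w^2) + 1 ).
#'
#' @param rho0 anticipated ICC, in (0, 1).
#' @param half_width desired CI half-width (> 0).
#' @param k number of repeated measurements per participant (>= 2).
#' @param alpha one minus the confidence level.
#' @return integer minimum sample size.
#' @export
sample_size_bonett <- function(rho0, half_width, k = 2, alpha = 0.05) {
  if (!(rho0 > 0 && rho0 < 1)) stop("rho0 must lie in (0, 1)")
  if (!(half_width > 0)) stop("half_width must be positive")
  if (k < 2) stop("k must be at least 2")
  w <- 2 * half_width
  z <- stats::qnorm(1 - alpha / 2)
  n <- 8 * z^2 * (1 - rho0)^2 * (1 + (k - 1) * rho0)^2 / (k * (k - 1) * w^2) + 1
  if (!is.finite(n)) stop("infeasible planning parameters")
  as.integer(ceiling(n))
}

#' Full agreement battery for one pair of measurement columns
#'
#' Convenience wrapper combining [icc_two_way_mixed()],
#' [spearman_bootstrap()] and [bland_altman()] on pairwise-complete data.
#'
#' @param x,y paired measurements; pairs with any missing value are dropped.
#' @param B,seed,conf bootstrap settings passed on.
#' @return list with elements `icc`, `spearman`, `bland_altman`, `n`,
#'   `n_dropped`.
#' @export
agreement_battery <- function(x, y, B = 2000, seed, conf = 0.95) {
  keep <- !(is.na(x) | is.na(y))
  xs <- x[keep]; ys <- y[keep]
  list(
    icc = icc_two_way_mixed(xs, ys, alpha = 1 - conf),
    spearman = spearman_bootstrap(xs, ys, B = B, seed = seed, conf = conf),
    bland_altman = bland_altman(xs, ys, conf = conf),
    n = sum(keep), n_dropped = sum(!keep)
  )
}
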