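# Lognormal summary statistics for sets of personal exposure measurements
# (8h-TWA concentrations in ppm).  All logarithms are natural; the GSD uses
# the sample (n-1) convention so that the grouped variance identities used by
# the evaluation module are exact.

#' Summarise a set of exposure measurements
#'
#' Computes n, arithmetic mean, geometric mean, geometric standard deviation
#' (sample, n-1 denominator; `NA` when n = 1), minimum and maximum for a
#' vector of positive concentrations.
#'
#' @param values Positive numeric vector of concentrations (ppm).
#' @param situation_id Optional identifier carried into the output.
#' @return A one-row data frame with columns `situation_id`, `n`, `am`, `gm`,
#'   `gsd`, `min`, `max`.
#' @examples
#' summarize_measurements(c(8.68, 41.89))   # gm 19.07, gsd 3.06
#' @export
summarize_measurements <- function(values, situation_id = "") {
  values <- as.numeric(values)
  if (length(values) < 1) stop_expoband("at least one measurement is required")
  if (any(!is.finite(values) | values <= 0)) {
    stop_expoband("all measurement values must be positive and finite")
  }
  lx <- log(values)
  n <- length(values)
  data.frame(
    situation_id = as.character(situation_id),
    n = n,
    am = mean(values),
    gm = exp(mean(lx)),
    gsd = if (n > 1) exp(sd(lx)) else NA_real_,
    min = min(values),
    max = max(values),
    stringsAsFactors = FALSE
  )
}

#' Closed-form lognormal 90th percentile
#'
#' `X_0.90 = GM * GSD^1.282`, with the exponent 1.282 used exactly as the
#' conventional rounded 90th-percentile z-value.
#'
#' @param gm Geometric mean (ppm).
#' @param gsd Geometric standard deviation (>= 1).  `NA` propagates (groups of
#'   size 1 have no spread estimate).
#' @return The 90th percentile (ppm), vectorised over inputs.
#' @examples
#' percentile90(13.07, 2.86)
#' @export
percentile90 <- function(gm, gsd) {
  gm <- as.numeric(gm)
  gsd <- as.numeric(gsd)
  if (any(!is.na(gm) & gm <= 0)) stop_expoband("gm must be positive")
  if (any(!is.na(gsd) & gsd < 1)) stop_expoband("gsd must be >= 1")
  gm * gsd^1.282
}

#' n-weighted pooled geometric mean
#'
#' `exp( sum(n_c * ln gm_c) / sum(n_c) )`: the geometric mean the pooled
#' individual data would have if each group's GM is exact.
#'
#' @param n Integer vector of group sizes.
#' @param gm Numeric vector of group geometric means (ppm).
#' @return Pooled GM (ppm).
#' @examples
#' pooled_geometric_mean(c(1, 1), c(4, 16))   # 8
#' @export
pooled_geometric_mean <- function(n, gm) {
  if (length(n) == 0) stop_expoband("no groups supplied")
  if (length(n) != length(gm)) stop_expoband("n and gm differ in length")
  if (any(n < 1)) stop_expoband("group sizes must be >= 1")
  if (any(!is.finite(gm) | gm <= 0)) stop_expoband("gm must be positive")
  exp(sum(n * log(gm)) / sum(n))
}

#' Log-scale moments of grouped measurement summaries
#'
#' For each group c with size n_c, geometric mean gm_c and sample GSD gsd_c,
#' returns the log-mean `m_c = ln gm_c` and the within-group sum of squares
#' `(n_c - 1) (ln gsd_c)^2`, which equals `sum_i (ln y_i - m_c)^2` exactly
#' under the n-1 GSD convention.  These moments let the evaluation module
#' reproduce individual-level statistics from summaries alone.
#'
#' @param n Integer vector of group sizes.
#' @param gm Numeric vector of group GMs (ppm).
#' @param gsd Numeric vector of group GSDs; may be `NA` where n = 1.
#' @return A list with `N` (total size), `m` (per-group log-means) and
#'   `within_ss` (per-group within sums of squares, 0 for n = 1 groups).
#' @export
grouped_log_moments <- function(n, gm, gsd) {
  if (length(n) != length(gm) || length(n) != length(gsd)) {
    stop_expoband("n, gm, gsd must have equal length")
  }
  if (any(n < 1)) stop_expoband("group sizes must be >= 1")
  if (any(n >= 2 & is.na(gsd))) {
    stop_expoband("gsd is missing for a group with n >= 2")
  }
  if (any(!is.na(gsd) & gsd < 1)) stop_expoband("gsd must be >= 1")
  list(
    N = sum(n),
    m = log(gm),
    within_ss = ifelse(n == 1, 0, (n - 1) * log(gsd)^2)
  )
}

#' Count exceedances of an occupational exposure limit
#'
#' @param values Positive numeric vector of measured concentrations (ppm).
#' @param oel Occupational exposure limit (ppm, 8h-TWA).
#' @return A list with `count` (values strictly above the limit) and
#'   `fraction` (count / n).
#' @examples
#' exceedance_count(c(1, 2, 3), oel = 2)
#' @export
exceedance_count <- function(values, oel) {
  if (missing(oel) || is.null(oel) || is.na(oel)) {
    stop_expoband("an exposure limit (oel) is required")
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop_expoband("all measurement values must be positive and finite")
  }
  count <- sum(values > oel)
  list(count = as.integer(count), fraction = count / length(values))
}
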