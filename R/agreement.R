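# Lack-of-agreement and correlation statistics between model estimates and
# measured exposures.  All inputs to the elementwise statistics are already
# natural-log transformed; residuals are d_i = est_ln_i - meas_ln_i (model
# minus measurement), so negative bias means the model underestimates.

check_pair <- function(est_ln, meas_ln) {
  if (length(est_ln) != length(meas_ln)) {
    stop_expoband("estimate and measurement vectors differ in length (",
                  length(est_ln), " vs ", length(meas_ln), ")")
  }
  if (length(est_ln) < 1) stop_expoband("at least one pair is required")
  if (any(!is.finite(est_ln)) || any(!is.finite(meas_ln))) {
    stop_expoband("inputs must be finite (already log-transformed)")
  }
  invisible(NULL)
}

#' Mean log-scale bias of model estimates
#'
#' `bias = mean(est_ln - meas_ln)` over matched pairs (ln ppm).
#'
#' @param est_ln Log-transformed model estimates.
#' @param meas_ln Log-transformed measured exposures, same length.
#' @return Bias in ln-ppm units.
#' @export
model_bias <- function(est_ln, meas_ln) {
  check_pair(est_ln, meas_ln)
  mean(est_ln - meas_ln)
}

#' Relative bias on the concentration scale
#'
#' `(exp(bias) - 1) * 100`, in percent.
#'
#' @param bias Log-scale bias (ln ppm).
#' @return Relative bias in percent.
#' @examples
#' relative_bias(-1)   # -63.21
#' @export
relative_bias <- function(bias) {
  (exp(bias) - 1) * 100
}

#' Precision of model estimates about their bias
#'
#' The square root of the mean squared deviation of the residuals about the
#' bias with an n-1 denominator: `sqrt(sum((d_i - bias)^2) / (n - 1))`, i.e.
#' the sample SD of the log-scale residuals, so that results read as
#' bias +/- precision on the same ln scale.
#'
#' @inheritParams model_bias
#' @param bias Optional precomputed bias; recomputed when `NULL`.
#' @return Precision in ln-ppm units.
#' @export
model_precision <- function(est_ln, meas_ln, bias = NULL) {
  check_pair(est_ln, meas_ln)
  n <- length(est_ln)
  if (n < 2) stop_expoband("precision needs at least two pairs")
  d <- est_ln - meas_ln
  b <- bias %||% mean(d)
  sqrt(sum((d - b)^2) / (n - 1))
}

#' Accuracy as mean absolute log error
#'
#' `mean(|est_ln - meas_ln|)` (MAE on the ln scale): the average distance
#' between estimated and measured exposures.
#'
#' @inheritParams model_bias
#' @return MAE in ln-ppm units.
#' @export
model_accuracy <- function(est_ln, meas_ln) {
  check_pair(est_ln, meas_ln)
  mean(abs(est_ln - meas_ln))
}

#' Residuals with Bland-Altman limits of agreement
#'
#' Residuals `d_i = est_ln_i - meas_ln_i` plus the mean difference and 95%
#' limits of agreement `mean +/- 1.96 * SD` (sample SD, n-1).
#'
#' @inheritParams model_bias
#' @return A list with `residuals`, `mean`, `sd`, `loa_lower`, `loa_upper`.
#' @export
model_residuals <- function(est_ln, meas_ln) {
  check_pair(est_ln, meas_ln)
  if (length(est_ln) < 2) stop_expoband("limits of agreement need n >= 2")
  d <- est_ln - meas_ln
  m <- mean(d)
  s <- sd(d)
  list(residuals = d, mean = m, sd = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' Bias reconstructed exactly from grouped summaries
#'
#' When every individual in group c shares the same estimate `a_c` and the
#' group GM is exact, the individual-level bias collapses to
#' `sum(n_c (a_c - ln gm_c)) / sum(n_c)`; this is bit-equal to [model_bias()]
#' on the underlying individual data.
#'
#' @param est_ln Per-group log estimates `a_c`.
#' @param n Group sizes.
#' @param gm Group geometric means (ppm).
#' @return Bias in ln-ppm units.
#' @export
grouped_bias <- function(est_ln, n, gm) {
  if (length(est_ln) != length(n) || length(n) != length(gm)) {
    stop_expoband("est_ln, n, gm must have equal length")
  }
  if (length(n) == 0) stop_expoband("no groups supplied")
  if (any(!is.finite(est_ln))) stop_expoband("estimates must be finite")
  sum(n * (est_ln - log(gm))) / sum(n)
}

#' Precision reconstructed exactly from grouped summaries
#'
#' Uses the exact decomposition
#' `sum_i_in_c (d_i - b)^2 = n_c (a_c - m_c - b)^2 + (n_c - 1)(ln gsd_c)^2`
#' (valid under the sample n-1 GSD convention), so the result equals
#' [model_precision()] on the underlying individual data.
#'
#' @inheritParams grouped_bias
#' @param gsd Group geometric standard deviations (`NA` allowed for n = 1).
#' @param bias Optional precomputed bias; recomputed via [grouped_bias()]
#'   when `NULL`.
#' @return Precision in ln-ppm units.
#' @export
grouped_precision <- function(est_ln, n, gm, gsd, bias = NULL) {
  mom <- grouped_log_moments(n, gm, gsd)
  if (length(est_ln) != length(n)) {
    stop_expoband("est_ln and n must have equal length")
  }
  if (mom$N < 2) stop_expoband("precision needs at least two measurements")
  b <- bias %||% grouped_bias(est_ln, n, gm)
  sqrt(sum(n * (est_ln - mom$m - b)^2 + mom$within_ss) / (mom$N - 1))
}

#' Approximate MAE from grouped summaries
#'
#' The exact mean absolute error requires individual data; under the
#' lognormal model the within-group residuals are Normal(mu_c, s_c^2) with
#' `mu_c = a_c - ln gm_c` and `s_c = ln gsd_c`, whose folded-normal mean is
#' `s sqrt(2/pi) exp(-mu^2 / 2 s^2) + mu (1 - 2 pnorm(-mu/s))`.  This is an
#' analytic approximation, not a reconstruction.
#'
#' @inheritParams grouped_precision
#' @return Approximate MAE in ln-ppm units.
#' @export
grouped_accuracy_approx <- function(est_ln, n, gm, gsd) {
  mom <- grouped_log_moments(n, gm, gsd)
  mu <- est_ln - mom$m
  s <- sqrt(mom$within_ss / pmax(n - 1, 1))
  e_abs <- ifelse(
    s == 0, abs(mu),
    s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) + mu * (1 - 2 * pnorm(-mu / s))
  )
  sum(n * e_abs) / mom$N
}

#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson r between two vectors (already on the scale to be
#' correlated, e.g. log-transformed concentrations or log-scale scores), with
#' the two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, non-constant.
#' @return A list with `r`, `n`, `p_value`.
#' @export
pearson_log <- function(x, y) {
  if (length(x) != length(y)) stop_expoband("x and y differ in length")
  if (length(x) < 3) stop_expoband("correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_expoband("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_expoband("zero variance: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Evaluate model estimates against measurements
#'
#' Produces an agreement report (overall and per task group) comparing one
#' estimate column against measured exposures.  Measurements may be given
#' either as grouped summaries (columns `situation_id`, `n`, `gm`, `gsd`),
#' in which case bias and precision are reconstructed exactly via the grouped
#' identities and the MAE is the analytic folded-normal approximation, or as
#' raw individual values (columns `situation_id`, `value_ppm`), in which case
#' all statistics, residuals and limits of agreement are exact.
#'
#' @param estimates Data frame with `situation_id`, an estimate column (ppm,
#'   or already-ln values if `estimates_are_log = TRUE`), and optionally the
#'   grouping column.
#' @param measurements Grouped summaries or raw measurements (see above).
#' @param column Name of the estimate column to evaluate (e.g. `"p50"`,
#'   `"p90"`, `"daily_average"`).
#' @param group_by Optional name of a column in `estimates` defining subgroup
#'   rows (default `"task"` when present).
#' @param estimates_are_log Set `TRUE` if the estimate column is already on
#'   the natural-log scale.
#' @return An object of class `evaluation_report`: a data frame with one row
#'   per group (first row `Overall`) and columns `group`, `n0`, `bias`,
#'   `relative_bias_pct`, `precision`, `accuracy`, `accuracy_method`.  When
#'   raw measurements are supplied the residual table (situation_id,
#'   residual) and limits of agreement are attached as attributes
#'   `residuals` and `loa`.
#' @examples
#' est <- load_fixture("model_estimates")
#' ms <- load_fixture("measurement_summaries")
#' evaluate_model(est, ms, column = "p90")
#' @export
evaluate_model <- function(estimates, measurements, column = "p50",
                           group_by = if ("task" %in% names(estimates)) "task",
                           estimates_are_log = FALSE) {
  if (!column %in% names(estimates)) {
    stop_expoband("estimates has no column '", column, "'")
  }
  if (!"situation_id" %in% names(estimates)) {
    stop_expoband("estimates needs a situation_id column")
  }
  raw_mode <- "value_ppm" %in% names(measurements)
  if (!raw_mode && !all(c("n", "gm") %in% names(measurements))) {
    stop_expoband("measurements must have value_ppm (raw) or n/gm/gsd (summary) columns")
  }
  if (raw_mode) {
    meas_ids <- unique(measurements$situation_id)
  } else {
    meas_ids <- measurements$situation_id
  }
  unmatched_est <- setdiff(estimates$situation_id, meas_ids)
  unmatched_meas <- setdiff(meas_ids, estimates$situation_id)
  common <- intersect(estimates$situation_id, meas_ids)
  if (length(common) == 0) {
    stop_expoband("no common situation_ids between estimates and measurements")
  }
  if (length(unmatched_est) || length(unmatched_meas)) {
    stop_expoband(
      "unmatched situation_ids - estimates only: {",
      paste(unmatched_est, collapse = ", "), "}; measurements only: {",
      paste(unmatched_meas, collapse = ", "), "}")
  }

  est <- estimates[match(common, estimates$situation_id), , drop = FALSE]
  a <- if (estimates_are_log) as.numeric(est[[column]]) else {
    v <- as.numeric(est[[column]])
    if (any(!is.finite(v) | v <= 0)) {
      stop_expoband("estimate column '", column,
                    "' must be positive to log-transform")
    }
    log(v)
  }

  groups <- list(Overall = seq_along(common))
  if (!is.null(group_by)) {
    for (gv in unique(est[[group_by]])) {
      groups[[as.character(gv)]] <- which(est[[group_by]] == gv)
    }
  }

  one_row <- function(label, idx) {
    if (raw_mode) {
      sub <- measurements[measurements$situation_id %in% common[idx], , drop = FALSE]
      a_i <- a[match(sub$situation_id, common)]
      y_i <- log(sub$value_ppm)
      b <- model_bias(a_i, y_i)
      data.frame(
        group = label, n0 = length(y_i), bias = b,
        relative_bias_pct = relative_bias(b),
        precision = if (length(y_i) >= 2) model_precision(a_i, y_i, b) else NA_real_,
        accuracy = model_accuracy(a_i, y_i),
        accuracy_method = "exact",
        stringsAsFactors = FALSE
      )
    } else {
      sm <- measurements[match(common[idx], measurements$situation_id), , drop = FALSE]
      b <- grouped_bias(a[idx], sm$n, sm$gm)
      data.frame(
        group = label, n0 = sum(sm$n), bias = b,
        relative_bias_pct = relative_bias(b),
        precision = if (sum(sm$n) >= 2)
          grouped_precision(a[idx], sm$n, sm$gm, sm$gsd, b) else NA_real_,
        accuracy = grouped_accuracy_approx(a[idx], sm$n, sm$gm, sm$gsd),
        accuracy_method = "folded-normal approximation",
        stringsAsFactors = FALSE
      )
    }
  }

  report <- do.call(rbind, lapply(names(groups), function(g) one_row(g, groups[[g]])))
  attr(report, "column") <- column
  if (raw_mode) {
    a_i <- a[match(measurements$situation_id, common)]
    res <- model_residuals(a_i, log(measurements$value_ppm))
    attr(report, "residuals") <- data.frame(
      situation_id = measurements$situation_id,
      residual = res$residuals, stringsAsFactors = FALSE)
    attr(report, "loa") <- res[c("mean", "sd", "loa_lower", "loa_upper")]
  }
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report> estimate column:", attr(x, "column"), "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  loa <- attr(x, "loa")
  if (!is.null(loa)) {
    cat(sprintf("limits of agreement: %.3f [%.3f, %.3f]\n",
                loa$mean, loa$loa_lower, loa$loa_upper))
  }
  invisible(x)
}
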