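test_that("bias, precision and accuracy follow their definitions", {
  y <- log(c(2, 5, 9, 14))
  expect_equal(model_bias(y, y), 0)
  expect_equal(model_bias(y + 0.5, y), 0.5)
  expect_error(model_bias(y, y[-1]), "length")
  expect_equal(model_precision(c(0, 2), c(1, 1)), sqrt(2))
  expect_equal(model_precision(y + 3, y), 0)
  expect_error(model_precision(1, 2), "at least two")
  expect_equal(model_accuracy(y, y), 0)
  expect_equal(model_accuracy(c(0, 2), c(1, 1)), 1)
  expect_equal(relative_bias(0), 0)
  expect_equal(relative_bias(-1), (exp(-1) - 1) * 100)
})

test_that("relative bias and bias are mutually inverse", {
  for (b in c(-2, -0.5, 0, 0.3, 1.7)) {
    expect_equal(log(1 + relative_bias(b) / 100), b, tolerance = 1e-12)
  }
})

test_that("accuracy dominates |bias| and precision is translation-invariant", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    est <- rnorm(n)
    meas <- rnorm(n)
    expect_gte(model_accuracy(est, meas), abs(model_bias(est, meas)) - 1e-12)
    shift <- runif(1, -3, 3)
    expect_equal(model_bias(est + shift, meas),
                 model_bias(est, meas) + shift, tolerance = 1e-12)
    expect_equal(model_precision(est + shift, meas),
                 model_precision(est, meas), tolerance = 1e-12)
  }
})

test_that("residuals carry Bland-Altman limits of agreement", {
  y <- c(0, 0, 0, 0)
  d <- c(0, 0, 2, -2)
  r <- model_residuals(d, y)
  expect_equal(r$residuals, d)
  expect_equal(r$mean, 0)
  expect_equal(r$loa_upper, 1.96 * sd(d))
  expect_equal(r$loa_lower, -1.96 * sd(d))
  same <- model_residuals(y, y)
  expect_equal(same$loa_upper, 0)
  # symmetric residuals have zero mean difference
  expect_equal(model_residuals(c(-1.3, 1.3), c(0, 0))$mean, 0)
})

test_that("grouped statistics equal individual-level statistics exactly", {
  # oracle equivalence on 100 seeded simulated datasets whose summaries use
  # the module's n-1 GSD convention
  set.seed(555)
  for (rep in 1:100) {
    k <- sample(3:8, 1)
    groups <- data.frame(
      situation_id = paste0("g", seq_len(k)),
      n = sample(1:12, k, replace = TRUE),
      gm = exp(runif(k, -2, 3)),
      gsd = exp(runif(k, 0.05, 1.2))
    )
    groups$gsd[groups$n == 1] <- NA
    sim <- simulate_measurements(groups, seed = rep)
    sm <- do.call(rbind, lapply(seq_len(k), function(i) {
      summarize_measurements(
        sim$value_ppm[sim$situation_id == groups$situation_id[i]],
        groups$situation_id[i])
    }))
    a <- rnorm(k)  # arbitrary per-group log estimates
    est_ind <- a[match(sim$situation_id, sm$situation_id)]
    y_ind <- log(sim$value_ppm)
    b_g <- grouped_bias(a, sm$n, sm$gm)
    expect_equal(b_g, model_bias(est_ind, y_ind), tolerance = 1e-12)
    if (sum(sm$n) >= 2) {
      expect_equal(grouped_precision(a, sm$n, sm$gm, sm$gsd),
                   model_precision(est_ind, y_ind), tolerance = 1e-9)
    }
  }
})

test_that("grouped bias is zero when each estimate equals its group GM", {
  expect_equal(grouped_bias(log(7.7), n = 5, gm = 7.7), 0)
  expect_error(grouped_bias(c(1, 2), n = 1, gm = 2), "equal length")
})

test_that("grouped MAE approximation matches the folded-normal oracle", {
  # large-n simulation converges to the analytic folded-normal mean
  groups <- data.frame(situation_id = "g", n = 2e4, gm = 10, gsd = 2.5)
  sim <- simulate_measurements(groups, seed = 31, exact_moments = TRUE)
  a <- log(18)
  exact <- model_accuracy(rep(a, nrow(sim)), log(sim$value_ppm))
  approx <- grouped_accuracy_approx(a, groups$n, groups$gm, groups$gsd)
  expect_equal(approx, exact, tolerance = 0.01)
})

test_that("pearson correlation is exact on affine relations and invariant", {
  x <- c(0.3, 1.7, 2.2, 5.0, 8.1)
  expect_equal(pearson_log(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_log(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2.5, 0.1, 3.3, 1.9, 4.4)
  r0 <- pearson_log(x, y)
  r1 <- pearson_log(3 * x + 7, 0.2 * y - 5)
  expect_equal(r0$r, r1$r, tolerance = 1e-12)
  expect_equal(r0$p_value, r1$p_value, tolerance = 1e-12)
  expect_error(pearson_log(x, rep(1, 5)), "zero variance")
  expect_error(pearson_log(x[1:2], y[1:2]), "n >= 3")
})

test_that("evaluate_model builds overall and per-task rows from summaries", {
  est <- load_fixture("model_estimates")
  ms <- load_fixture("measurement_summaries")
  rep50 <- evaluate_model(est, ms, column = "p50")
  expect_identical(rep50$group, c("Overall", "FRP lamination", "Inspection"))
  expect_identical(rep50$n0, c(160L, 137L, 23L))
  # report rows agree with direct grouped computations
  expect_equal(rep50$bias[1], grouped_bias(log(est$p50), ms$n, ms$gm),
               tolerance = 1e-12)
  f <- ms$task == "FRP lamination"
  expect_equal(rep50$bias[2], grouped_bias(log(est$p50[f]), ms$n[f], ms$gm[f]),
               tolerance = 1e-12)
  expect_equal(rep50$precision[1],
               grouped_precision(log(est$p50), ms$n, ms$gm, ms$gsd),
               tolerance = 1e-12)
  # self-comparison: estimates equal to the measurement GMs give zero bias
  self <- est
  self$p50 <- ms$gm[match(est$situation_id, ms$situation_id)]
  rep_self <- evaluate_model(self, ms, column = "p50")
  expect_equal(rep_self$bias, rep(0, 3), tolerance = 1e-12)
})

test_that("evaluate_model on raw measurements is exact and carries residuals", {
  est <- load_fixture("model_estimates")
  ms <- load_fixture("measurement_summaries")
  sim <- simulate_measurements(ms, seed = 17, exact_moments = TRUE)
  rep_raw <- evaluate_model(est, sim, column = "p90")
  rep_sum <- evaluate_model(est, ms, column = "p90")
  # exact-moments simulation makes raw and grouped routes agree
  expect_equal(rep_raw$bias, rep_sum$bias, tolerance = 1e-9)
  expect_equal(rep_raw$precision, rep_sum$precision, tolerance = 1e-9)
  expect_identical(rep_raw$accuracy_method[1], "exact")
  res <- attr(rep_raw, "residuals")
  expect_equal(nrow(res), 160)
  loa <- attr(rep_raw, "loa")
  expect_equal(loa$loa_upper, loa$mean + 1.96 * loa$sd)
  expect_gte(rep_raw$accuracy[1], abs(rep_raw$bias[1]))
})

test_that("evaluate_model rejects mismatched situation ids", {
  est <- load_fixture("model_estimates")
  ms <- load_fixture("measurement_summaries")
  est_bad <- est
  est_bad$situation_id[1] <- "FRP-ZZ"
  err <- expect_error(evaluate_model(est_bad, ms, column = "p50"), "unmatched")
  expect_match(conditionMessage(err), "FRP-ZZ", fixed = TRUE)
  ms_alien <- ms
  ms_alien$situation_id <- paste0("x", ms$situation_id)
  expect_error(evaluate_model(est, ms_alien, column = "p50"), "no common")
})
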