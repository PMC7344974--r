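test_that("worked FRP-lamination profile scores 6.32, category 3", {
  prof <- load_fixture("worked_profile")
  res <- compute_exposure_score(prof)
  expect_equal(res$breakdown$applied_score,
               c(2.0, 3.0, 2.0, 2.0, 1.2, 2.0, 2.0, 4.0, 2.0, 3.0, 2.0, 10.0))
  expect_equal(res$raw_product, 552.96, tolerance = 1e-12)
  expect_equal(res$score, log(552.96), tolerance = 1e-12)
  expect_equal(res$score_2dp, 6.32)
  expect_identical(res$category, 3L)
  expect_false(res$clamped)
})

test_that("no-exposure convention: trivial profile scores 1.00 in category 1", {
  res <- compute_exposure_score(no_exposure_profile())
  expect_equal(res$score, 1.00)
  expect_identical(res$category, 1L)
  expect_true(res$all_no_exposure)
  expect_equal(score_breakdown(res)$log_contribution, rep(0, 12))
})

test_that("non-trivial low profiles are clamped to 1.01 (category 2)", {
  ne <- no_exposure_profile()
  sel <- ne$selections
  sel$room_volume <- ">1000 m3"   # raw product 1/10, ln negative
  res <- compute_exposure_score(situation_profile(sel, phase = "liquid"))
  expect_true(res$clamped)
  expect_equal(res$score, 1.01)
  expect_identical(res$category, 2L)
})

test_that("maximal profile attains the category-4 upper limit", {
  expect_equal(round(max_attainable_score(ft_default), 2), 14.01)
  expect_equal(max_attainable_score(ft_default),
               log(3 * 5 * 5 * 2 * 3 * 3 * 5 * 6 * 3 * 5 * 2 / 1),
               tolerance = 1e-12)
  # brute-force enumeration over all attainable products agrees
  prods <- attainable_raw_products(ft_default)
  expect_equal(log(max(prods)), max_attainable_score(ft_default),
               tolerance = 1e-9)
  expect_true(all(log(prods) <= max_attainable_score(ft_default) + 1e-9))
})

test_that("category bands are contiguous, total, and match the band geometry", {
  b <- bands_default
  expect_identical(b$category, 1:4)
  expect_equal(b$lower, c(1.00, 1.01, 4.77, 9.39))
  expect_equal(b$upper, c(1.00, 4.76, 9.38, 14.01))
  expect_identical(assign_category(c(6.32, 1.00, 10.57, 4.76, 4.77)),
                   c(3L, 1L, 4L, 2L, 3L))
  # half-up rounding at the 2-dp gaps
  expect_identical(assign_category(4.764), 2L)
  expect_identical(assign_category(4.765), 3L)
  expect_error(assign_category(14.2), "inconsistent")
  mx <- max_attainable_score(ft_default)
  expect_lt(abs(b$upper[2] - 0.34 * mx), 0.01)
  expect_lt(abs(b$upper[3] - 0.67 * mx), 0.01)
})

test_that("scoring equals independent direct formula evaluation on random profiles", {
  set.seed(42)
  for (i in 1:1000) {
    phase <- if (i %% 2) "liquid" else "solid"
    prof <- random_profile(phase = phase)
    res <- compute_exposure_score(prof)
    ln <- direct_ln_score(prof)
    expect_equal(log(res$raw_product), ln, tolerance = 1e-12)
    expect_gte(res$score, 1.00)
    expect_lte(res$score, max_attainable_score(ft_default, phase) + 1e-9)
  }
})

test_that("raising a multiplier score increases the score; the divisor decreases it", {
  set.seed(7)
  ft <- ft_default
  for (i in 1:50) {
    prof <- random_profile()
    base <- compute_exposure_score(prof)
    for (id in FACTOR_IDS) {
      f <- ft$factors[[id]]
      cls <- f$classifications
      if (f$phase_dependent) cls <- cls[cls$phase %in% "liquid", , drop = FALSE]
      cur <- cls$score[match(prof$selections[[id]], cls$label)]
      higher <- cls[cls$score > cur, , drop = FALSE]
      if (nrow(higher) == 0) next
      sel <- prof$selections
      sel[[id]] <- higher$label[sample.int(nrow(higher), 1)]
      alt <- compute_exposure_score(situation_profile(sel, phase = "liquid"))
      if (f$role == "divisor") {
        expect_lt(alt$raw_product, base$raw_product)
      } else {
        expect_gt(alt$raw_product, base$raw_product)
      }
    }
  }
})

test_that("breakdown contributions sum to the log raw product", {
  set.seed(11)
  for (i in 1:25) {
    res <- compute_exposure_score(random_profile())
    b <- score_breakdown(res)
    expect_equal(sum(b$log_contribution), log(res$raw_product),
                 tolerance = 1e-9)
    expect_equal(b$log_contribution[b$factor_id == "room_volume"],
                 -log(b$applied_score[b$factor_id == "room_volume"]))
  }
})

test_that("batch scoring is fail-fast with an aggregated error report", {
  prof <- load_fixture("worked_profile")
  good <- score_profiles(list(prof, no_exposure_profile()))
  expect_equal(nrow(good), 2)
  expect_equal(good$score_2dp, c(6.32, 1.00))
  bad <- prof
  bad$selections$ppe <- "complete protection"
  bad2 <- prof
  bad2$selections$distance <- "2 miles"
  err <- expect_error(score_profiles(list(prof, bad, bad2)), "invalid profile")
  expect_match(conditionMessage(err), "complete protection", fixed = TRUE)
  expect_match(conditionMessage(err), "2 miles", fixed = TRUE)
  empty <- score_profiles(list())
  expect_equal(nrow(empty), 0)
})
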