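test_that("cohort accounting reproduces the printed cohort percentages", {
  acc <- cohort_accounting(recruited = 174, unanalyzable = 62, cystic = 25,
                           analyzed = 87, never_rop = 57, always_rop = 19,
                           mixed_rop = 11)
  pct <- setNames(acc$percent, acc$group)
  expect_equal(pct[["unanalyzable"]], 36L)
  expect_equal(pct[["cystic"]], 14L)
  expect_equal(pct[["never_rop"]], 65L)
  expect_equal(pct[["always_rop"]], 22L)
  expect_equal(pct[["mixed_rop"]], 13L)
  # each family partitions its denominator, so percentages sum to 100
  expect_equal(sum(pct[c("unanalyzable", "cystic", "analyzed")]), 100L)
  expect_equal(sum(pct[c("never_rop", "always_rop", "mixed_rop")]), 100L)
})

test_that("zero counts give 0% and inconsistent counts raise accounting errors", {
  acc <- cohort_accounting(100, 0, 0, 100, 100, 0, 0)
  expect_equal(acc$percent[acc$group == "unanalyzable"], 0L)
  expect_error(cohort_accounting(174, 62, 25, 80, 57, 19, 11),
               "accounting error")
  expect_error(cohort_accounting(174, 62, 25, 87, 57, 19, 5),
               "accounting error")
  expect_error(cohort_accounting(174, -1, 26, 149, 100, 30, 19),
               "non-negative")
})

test_that("a noiseless cohort returns the generating slopes to machine precision", {
  spec <- cohort_spec(n_infants = 15, between_infant_sd = 0, residual_sd = 0,
                      eyes = "right", seed = 5)
  tab <- gen_cohort(spec)$table
  res <- fit_mixed_model(tab, "width", adjustment = "ga")
  sl <- setNames(res$slopes$estimate, res$slopes$group)
  expect_equal(sl[["absent"]], -11.18, tolerance = 1e-8)
  expect_equal(sl[["present"]], 24.96, tolerance = 1e-8)
  # and the 32-week predicted means equal the generating intercepts
  pm <- predict_means(res, list(list(pma = 32, rop = "present"),
                                list(pma = 32, rop = "absent")))
  expect_equal(pm$estimate, c(1203.6, 1584.9), tolerance = 1e-6)
  expect_equal(attr(pm, "ratio_pct"), 76L)
})

test_that("the default synthetic cohort recovers both group slopes within 2 SE", {
  sim <- gen_cohort(cohort_spec(n_infants = 80, seed = 1))
  res <- fit_mixed_model(sim$table, "width", adjustment = "ga")
  expect_true(res$converged)
  sl <- res$slopes
  expect_lt(abs(sl$estimate[sl$group == "absent"] - (-11.18)),
            2 * sl$se[sl$group == "absent"])
  expect_lt(abs(sl$estimate[sl$group == "present"] - 24.96),
            2 * sl$se[sl$group == "present"])
  # the interaction the effect was generated under is detected
  int_p <- res$fixed$p[grepl("^pma_c:rop", res$fixed$term)]
  expect_lt(int_p, 0.001)
})

test_that("GA and BW act as separate predictor models, never together", {
  tab <- gen_cohort(cohort_spec(n_infants = 20, seed = 2))$table
  res_ga <- fit_mixed_model(tab, "width", adjustment = "ga")
  res_bw <- fit_mixed_model(tab, "width", adjustment = "bw")
  expect_true("ga" %in% res_ga$fixed$term)
  expect_false("bw" %in% res_ga$fixed$term)
  expect_true("bw" %in% res_bw$fixed$term)
  expect_false("ga" %in% res_bw$fixed$term)
})

test_that("sided responses model nasal and temporal jointly with a side factor", {
  tab <- gen_cohort(cohort_spec(n_infants = 20, seed = 7))$table
  res <- fit_mixed_model(tab, "prt", adjustment = "ga", sided = TRUE)
  expect_true(any(grepl("^side", res$fixed$term)))
  expect_equal(res$n_obs, 2 * sum(!is.na(tab$prt_nasal)))
  # the generated nasal-thicker offset (2 x 10 µm) is recovered
  side_row <- grepl("^side", res$fixed$term)
  expect_lt(abs(abs(res$fixed$estimate[side_row]) - 20), 3)
})

test_that("quadratic PMA trends are picked up for the curvature parameters", {
  tab <- gen_cohort(cohort_spec(n_infants = 40, seed = 9))$table
  res <- fit_mixed_model(tab, "depth", adjustment = "ga", quadratic_pma = TRUE)
  quad <- res$fixed[res$fixed$term == "I(pma_c^2)", ]
  expect_lt(abs(quad$estimate - (-0.12)), 2 * quad$se + 0.02)
  expect_lt(quad$p, 0.05)
})

test_that("predicted-mean ratios are invariant to response rescaling", {
  tab <- gen_cohort(cohort_spec(n_infants = 25, seed = 3))$table
  res_um <- fit_mixed_model(tab, "width", adjustment = "ga")
  tab_mm <- tab
  tab_mm$width <- tab_mm$width / 1000
  res_mm <- fit_mixed_model(tab_mm, "width", adjustment = "ga")
  prof <- list(list(pma = 32, rop = "present"), list(pma = 32, rop = "absent"))
  expect_equal(attr(predict_means(res_um, prof), "ratio_pct"),
               attr(predict_means(res_mm, prof), "ratio_pct"))
  # identical profiles give 100%
  same <- predict_means(res_um, list(list(pma = 33, rop = "absent"),
                                     list(pma = 33, rop = "absent")))
  expect_equal(attr(same, "ratio_pct"), 100L)
})

test_that("predictions outside the observed PMA range are flagged as extrapolation", {
  tab <- gen_cohort(cohort_spec(n_infants = 15, seed = 4))$table
  res <- fit_mixed_model(tab, "width", adjustment = "ga")
  expect_warning(
    pm <- predict_means(res, list(list(pma = 50, rop = "absent"),
                                  list(pma = 32, rop = "absent"))),
    "extrapolation")
  expect_true(pm$extrapolated[1])
  expect_false(pm$extrapolated[2])
})

test_that("percent_ratio applies half-up integer rounding", {
  expect_equal(percent_ratio(1203.6, 1584.9), 76L)
  expect_equal(percent_ratio(1, 1), 100L)
  expect_equal(percent_ratio(765, 1000), 77L)  # 76.5 rounds half-up
})

test_that("the 2x2 chi-square matches the hand formula and rejects degenerate tables", {
  # no association: equal inversion proportions in both groups
  none <- chi_square_2x2(matrix(c(30, 10, 30, 10), 2))
  expect_equal(none$statistic, 0, tolerance = 1e-12)
  expect_equal(none$p_value, 1, tolerance = 1e-12)

  tab <- matrix(c(30, 20, 10, 20), 2)  # [[30,10],[20,20]] in row form
  got <- chi_square_2x2(tab)
  # hand oracle: sum (O - E)^2 / E with E from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_lt(got$p_value, 0.05)

  expect_error(chi_square_2x2(matrix(c(0, 0, 10, 20), 2)), "margin")
})

test_that("rows excluded for quality or cysts never enter the models", {
  sim <- gen_cohort(cohort_spec(n_infants = 20, prop_poor_quality = 0.15,
                                prop_cystic = 0.05, seed = 6))
  tab <- sim$table
  n_excl <- sum(tab$poor_quality | tab$cystic)
  expect_gt(n_excl, 0)
  expect_true(all(is.na(tab$width[tab$poor_quality | tab$cystic])))
  res <- fit_mixed_model(tab, "width", adjustment = "ga")
  expect_equal(res$n_obs, nrow(tab) - n_excl)
})
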