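toy_records <- function(age, diff, forest = TRUE) {
  data.frame(pa_id = seq_along(age), status_year = 2000 - age,
             pa_age_years = age, baseline_diff = diff,
             forest_flag = forest, n_pairs = 5L,
             group = ifelse(2000 - age >= 2000, "recent", "older"))
}

test_that("baseline differences are paired and grouped by establishment era", {
  cells <- manual_cells(data.frame(cell_id = 1:6,
                                   baseline_agcd_2000 = c(50, 60, 70, 50, 55, 65)))
  pairs <- data.frame(pa_cell_id = 1:3, control_cell_id = 4:6,
                      pa_id = c(1L, 1L, 2L))
  pas <- data.frame(pa_id = 1:2, status_yr = c(1980L, 2005L),
                    forest_flag = c(TRUE, FALSE))
  rec <- baseline_differences(pairs, cells, pas)
  expect_equal(rec$baseline_diff, c(mean(c(0, 5)), 5))
  expect_identical(rec$group, c("older", "recent"))
  expect_equal(rec$pa_age_years, c(20, -5))

  # identical baselines give zero differences
  cells0 <- manual_cells(data.frame(cell_id = 1:6, baseline_agcd_2000 = 42))
  expect_equal(baseline_differences(pairs, cells0, pas)$baseline_diff,
               c(0, 0))

  # group means on a 3-PA toy table match hand arithmetic
  rec3 <- toy_records(age = c(30, 10, -5), diff = c(6, 4, 1))
  gs <- baseline_group_summary(rec3)
  expect_equal(gs$by_group$mean_diff[gs$by_group$group == "older"], 5)
  expect_equal(gs$by_group$mean_diff[gs$by_group$group == "recent"], 1)
  expect_equal(gs$recent_to_older_ratio, 0.2)
})

test_that("age regression matches the closed-form normal equations", {
  # exactly linear, zero noise: slope recovered to numerical precision
  rec <- toy_records(age = c(-10, 0, 10, 20, 40), diff = 2 + 0.3 * c(-10, 0, 10, 20, 40))
  fit <- age_regression(rec)
  expect_equal(fit$slope, 0.3, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-10)

  # five-point toy set against the lm oracle
  set.seed(5)
  rec2 <- toy_records(age = c(-3, 5, 12, 30, 55), diff = rnorm(5, 3, 2))
  fit2 <- age_regression(rec2)
  lmfit <- lm(baseline_diff ~ pa_age_years, data = rec2)
  expect_equal(fit2$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit2$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  expect_equal(fit2$se_slope,
               unname(summary(lmfit)$coefficients[2, 2]), tolerance = 1e-12)
  expect_equal(fit2$p_value,
               unname(summary(lmfit)$coefficients[2, 4]), tolerance = 1e-12)

  # antisymmetry: negating the differences negates the slope
  rec_neg <- transform(rec2, baseline_diff = -baseline_diff)
  expect_equal(age_regression(rec_neg)$slope, -fit2$slope)

  expect_error(age_regression(toy_records(age = rep(10, 5), diff = 1:5)),
               "degenerate")
  expect_error(age_regression(toy_records(age = c(1, 2), diff = c(1, 2))),
               "at least 3")
})

test_that("slope test keeps nominal size under the null", {
  # Monte-Carlo oracle: age-independent differences should reject ~5%
  set.seed(99)
  reject <- vapply(1:400, function(i) {
    rec <- toy_records(age = seq(-10, 50, length.out = 12),
                       diff = rnorm(12))
    age_regression(rec)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("pre-2000 protection growth appears in older but not recent PAs", {
  recs <- do.call(rbind, lapply(1:4, function(s) {
    run <- run_pipeline(run_config(
      landscape = reduced_config(seed = s, baseline_growth_rate = 0.3)))
    run$baseline$records
  }))
  older <- recs$baseline_diff[recs$group == "older"]
  recent <- recs$baseline_diff[recs$group == "recent"]
  expect_gt(mean(older), mean(recent))
  expect_gt(mean(older), 0)
  # and age carries a positive slope overall
  expect_gt(age_regression(recs)$slope, 0)
})

test_that("forest stratification runs separately per stratum", {
  rec <- rbind(toy_records(age = c(0, 10, 20, 30), diff = c(1, 2, 3, 4),
                           forest = TRUE),
               toy_records(age = c(5, 15, 25), diff = c(2, 2.2, 2.4),
                           forest = FALSE))
  fits <- age_regression(rec, by_forest = TRUE)
  expect_equal(fits$forest$slope, 0.1, tolerance = 1e-9)
  expect_equal(fits$nonforest$slope, 0.02, tolerance = 1e-9)
  expect_identical(fits$all$n, 7L)
})
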