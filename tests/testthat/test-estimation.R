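test_that("overlapping protected areas are dissolved and counted once", {
  a <- data.frame(pa_id = 1L, cell_id = 1:100)
  b <- data.frame(pa_id = 2L, cell_id = 71:170)  # 30 shared with a
  d <- dissolve_pa_area(rbind(a, b))
  expect_equal(d$total_km2, 170)
  expect_equal(d$per_pa$area_km2_raw, c(100, 100))
  expect_equal(d$per_pa$area_km2_exclusive, c(100, 70))

  disj <- dissolve_pa_area(data.frame(pa_id = rep(1:2, c(10, 20)),
                                      cell_id = 1:30))
  expect_equal(disj$total_km2, 30)

  nested <- dissolve_pa_area(data.frame(pa_id = rep(1:2, c(100, 10)),
                                        cell_id = c(1:100, 41:50)))
  expect_equal(nested$total_km2, 100)
  expect_equal(nested$per_pa$area_km2_exclusive[2], 0)
})

test_that("hybrid variance combines sampling and model components", {
  h <- hybrid_mean_se(c(10, 20, 30), model_rel_se = 0)
  expect_equal(h$mean, 20)
  expect_equal(h$se, 10 / sqrt(3))

  h2 <- hybrid_mean_se(rep(50, 4), model_rel_se = 0.1)
  expect_equal(h2$se, 5)  # sampling term zero, model term 0.1 * 50

  set.seed(2)
  x <- rnorm(20, 100, 15)
  h3 <- hybrid_mean_se(x, model_rel_se = 0.03)
  expect_equal(h3$se^2, h3$var_sampling + h3$var_model, tolerance = 1e-12)

  h4 <- hybrid_mean_se(7)
  expect_true(h4$low_confidence)
  expect_true(is.na(h4$se))
})

test_that("paired stratum differences have the closed-form mean and SE", {
  cm <- data.frame(cell_id = 1:6,
                   mean_agcd = c(12, 14, 16, 10, 10, 10),
                   mean_agbd = c(12, 14, 16, 10, 10, 10) / 0.49,
                   mean_rh98 = 1:6, mean_cover = (1:6) / 10,
                   mean_pai = 1:6)
  pairs <- data.frame(pa_cell_id = 1:3, control_cell_id = 4:6,
                      pa_id = 1L, country = 1L, biome = 1L, continent = 1L,
                      land_cover = 1L, ecoregion = 1L)
  sd1 <- stratum_difference(pairs, cm, by = "pa_id")
  expect_equal(sd1$mean_diff, 4)          # d = {2, 4, 6}
  expect_equal(sd1$se_diff, 2 / sqrt(3))
  expect_equal(sd1$n_pairs, 3L)

  # swapping PA and control labels negates the mean difference
  swapped <- transform(pairs, pa_cell_id = control_cell_id,
                       control_cell_id = pa_cell_id)
  sd2 <- stratum_difference(swapped, cm, by = "pa_id")
  expect_equal(sd2$mean_diff, -sd1$mean_diff)
  expect_equal(sd2$se_diff, sd1$se_diff)

  # single-pair strata are flagged low confidence
  sd3 <- stratum_difference(pairs[1, ], cm, by = "pa_id")
  expect_true(sd3$low_confidence)
  expect_true(is.na(sd3$se_diff))
})

test_that("area expansion converts Mg C/ha over km2 to Gt linearly", {
  e <- expand_to_total(10, 1, 1000)
  expect_equal(e$total_gt, 0.001)
  expect_equal(e$se_gt, 1e-4)
  expect_equal(expand_to_total(10, 1, 0)$total_gt, 0)
  expect_equal(expand_to_total(10, 1, 2000)$total_gt, 2 * e$total_gt)
  expect_error(expand_to_total(10, 1, -5), "non-negative")
  # dimensional round trip on random values
  set.seed(4)
  m <- runif(20, 0, 200); a <- runif(20, 0, 1e4)
  expect_equal(expand_to_total(m, m / 10, a)$total_gt / (a * 100 * 1e-9), m)
})

test_that("unmatched PAs inherit country-biome then continent-biome results", {
  cb <- data.frame(country = 1L, biome = 1L, n_pairs = 10L,
                   mean_agcd_pa = 60, mean_agcd_control = 55,
                   mean_diff = 5, se_diff = 1)
  contb <- data.frame(continent = 1L, biome = 2L, n_pairs = 4L,
                      mean_agcd_pa = 30, mean_agcd_control = 28,
                      mean_diff = 2, se_diff = 0.5)
  pas <- data.frame(pa_id = 1:3, country = c(1L, 2L, 2L),
                    continent = c(1L, 1L, 1L), biome = c(1L, 2L, 3L))
  ext <- extrapolate_unmatched(pas, cb, contb)
  expect_identical(ext$provenance,
                   c("extrapolated_country_biome",
                     "extrapolated_continent_biome", "no_estimate"))
  expect_equal(ext$mean_diff, c(5, 2, NA))
  # composition with area expansion: 5 Mg C/ha over 200 km2
  add <- expand_to_total(ext$mean_diff[1], ext$se_diff[1], 200)
  expect_equal(add$total_gt, 1e-4)
})

test_that("aggregation sums totals and combines SEs as independent", {
  cont <- data.frame(
    continent = c("SA", "AS", "AF", "NA", "OC", "EU"),
    additional_gt = c(4.94, 1.38, 1.2, 0.86, 0.65, 0.61),
    se_additional_gt = c(0.47, 0.59, 0.17, 0.33, 0.32, 0.13)
  )
  g <- aggregate_estimates(cont, "globe")
  expect_equal(g$additional_gt, 9.64)  # the printed global total
  one <- aggregate_estimates(cont[1, ], "globe")
  expect_equal(one$additional_gt, cont$additional_gt[1])
  expect_equal(one$se_additional_gt, cont$se_additional_gt[1])

  two <- aggregate_estimates(
    data.frame(additional_gt = c(1, 1), se_additional_gt = c(0.3, 0.4)),
    "globe")
  expect_equal(two$se_additional_gt, 0.5)
})

test_that("pipeline totals are additive across aggregation levels", {
  run <- run_pipeline(run_config(landscape = tiny_config(seed = 6)))
  est <- run$estimates
  expect_equal(sum(est$by_continent$additional_gt), est$globe$additional_gt,
               tolerance = 1e-12)
  expect_equal(sum(est$by_country$additional_gt), est$globe$additional_gt,
               tolerance = 1e-12)
  expect_equal(sum(est$by_biome$additional_gt), est$globe$additional_gt,
               tolerance = 1e-12)
  expect_equal(sum(est$by_continent$area_km2), est$globe$area_km2)
  # SEs combine quadratically across disjoint strata
  expect_equal(est$globe$se_additional_gt,
               sqrt(sum(est$stratum_table$se_additional_gt^2, na.rm = TRUE)),
               tolerance = 1e-12)
})
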