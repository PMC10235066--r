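test_that("identical config and seed give bit-identical landscapes and footprints", {
  cfg <- tiny_config(seed = 42)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$pas, b$pas)
  expect_identical(a$truth, b$truth)
  expect_identical(sample_footprints(a), sample_footprints(b))
})

test_that("unconfounded placement leaves protected and unprotected covariates similar", {
  # placement is cluster-level, so finite-grid SMDs are noisy; they shrink
  # with more, larger samples and must be far below the confounded case
  smd_max <- function(cs, seed) {
    ls <- generate_landscape(landscape_config(
      grid_rows = 90, grid_cols = 90, n_pas = 16,
      confounding_strength = cs, seed = seed))
    tr <- ls$cells[ls$cells$is_protected, ]
    co <- ls$cells[!ls$cells$is_protected, ]
    max(abs(vapply(pa_covariates(),
                   function(v) pacarbon:::smd(tr[[v]], co[[v]]), numeric(1))))
  }
  s0 <- mean(vapply(1:3, function(s) smd_max(0, s), numeric(1)))
  s2 <- mean(vapply(1:3, function(s) smd_max(2, s), numeric(1)))
  expect_lt(s0, 0.25)
  expect_lt(s0, s2)
})

test_that("a null effect with unconfounded placement gives near-zero truth-field contrast", {
  # oracle: direct means over the generated truth field
  diffs <- vapply(1:10, function(s) {
    ls <- generate_landscape(tiny_config(seed = s, pa_effect_delta = 0,
                                         confounding_strength = 0,
                                         loss_rate_protected = 0.03,
                                         loss_rate_unprotected = 0.03))
    prot <- ls$cells$is_protected
    mean(ls$truth$agbd_expected[prot]) - mean(ls$truth$agbd_expected[!prot])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)) + 1)
})

test_that("infeasible protected-area layouts raise a sizing error", {
  expect_error(landscape_config(grid_rows = 10, grid_cols = 10, n_pas = 10),
               "grid too small")
  expect_error(landscape_config(grid_rows = 5, n_pas = 0), "count >= 1")
  expect_error(landscape_config(loss_rate_protected = 1.2), "\\[0, 1\\]")
  expect_error(landscape_config(track_spacing_m = 0), "> 0")
})

test_that("track geometry matches the configured spacing", {
  cfg <- tiny_config(seed = 3, track_dropout_rate = 0, p_bad_quality = 0)
  ls <- generate_landscape(cfg)
  fp <- sample_footprints(ls)
  # 40 km wide grid at 0.6 km spacing: 66 or 67 tracks
  n_tracks <- length(unique(fp$track_id))
  expect_true(abs(n_tracks - 40 / 0.6) <= 1)
  # along-track spacing is 60 m
  one <- fp[fp$track_id == fp$track_id[1], ]
  expect_equal(unique(round(diff(sort(one$y)), 9)), 0.06)
})

test_that("noise-free shots equal their cell expectation", {
  cfg <- tiny_config(seed = 5, shot_noise_sd = 0, p_bad_quality = 0)
  ls <- generate_landscape(cfg)
  fp <- sample_footprints(ls)
  expect_lt(max(abs(fp$agbd - ls$truth$agbd_expected[fp$cell_id])), 1e-9)
  expect_true(all(fp$quality_flag == 1))
})

test_that("per-cell shot counts match point-in-cell counting and are non-degenerate", {
  cfg <- tiny_config(seed = 7)
  ls <- generate_landscape(cfg)
  fp <- sample_footprints(ls)
  # independent oracle: recompute the containing cell from coordinates
  oracle_cell <- floor(fp$y) * cfg$grid_cols + floor(fp$x) + 1
  expect_identical(fp$cell_id, as.integer(oracle_cell))
  counts <- tabulate(fp$cell_id, nbins = nrow(ls$cells))
  expect_gt(stats::var(counts), 0)
  expect_gt(sum(counts < 5), 0)  # dropout creates under-sampled cells
  expect_true(all(fp$sensitivity >= 0 & fp$sensitivity <= 1))
  expect_true(all(fp$canopy_cover >= 0 & fp$canopy_cover <= 1))
  expect_true(all(fp$agbd >= 0))
})

test_that("written landscapes round-trip and the manifest records the seed", {
  cfg <- tiny_config(seed = 11)
  ls <- generate_landscape(cfg)
  fp <- sample_footprints(ls)
  dir <- withr::local_tempdir()
  write_landscape(ls, dir, footprints = fp)
  back <- read_landscape(dir, with_truth = TRUE)
  expect_equal(back$cells, ls$cells, tolerance = 1e-8)
  expect_equal(back$pas, ls$pas, tolerance = 1e-8)
  expect_equal(back$truth, ls$truth, tolerance = 1e-8)
  expect_equal(back$footprints, fp, tolerance = 1e-8)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(as.integer(manifest$seed), cfg$seed)
  expect_identical(manifest$config$grid_rows, cfg$grid_rows)

  gj <- jsonlite::read_json(file.path(dir, "pas.geojson"),
                            simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(ls$pas))
  f1 <- gj$features[[1]]
  expect_identical(f1$type, "Feature")
  expect_identical(f1$geometry$type, "MultiPolygon")
  expect_true(all(c("pa_id", "status_yr", "country", "area_km2") %in%
                    names(f1$properties)))
  # each PA's polygon count equals its member-cell count
  expect_equal(length(f1$geometry$coordinates), f1$properties$area_km2)
})
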