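test_that("control pool honours the buffer and full-coverage rules", {
  cells <- manual_cells(data.frame(
    x = c(5.5, 10.5, 20.5, 6.5, 5.5),
    y = c(5.5, 5.5, 5.5, 5.5, 7.5),
    row = c(6, 6, 6, 6, 8), col = c(6, 11, 21, 7, 6),
    is_protected = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    pa_id = c(1L, NA, NA, 1L, NA),
    pa_cover_fraction = c(1, 0, 0, 0.6, 0)
  ))
  pas <- data.frame(pa_id = 1L)
  pools <- build_control_pool(cells, pas, buffer_km = 10)
  # protected cell with partial coverage (straddling the boundary) excluded
  expect_identical(pools$treated$cell_id, 1L)
  # unprotected cell ~5 km from the PA: buffered out; ~15 km: eligible
  expect_false(2L %in% pools$controls$cell_id)
  expect_true(3L %in% pools$controls$cell_id)
  # cell adjacent to the PA (distance ~2 km) also buffered out
  expect_false(5L %in% pools$controls$cell_id)
  expect_identical(pools$n_buffer_excluded, 2L)
})

test_that("propensity fit is symmetric, monotone, and matches a Newton oracle", {
  set.seed(10)
  n <- 1000
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(X) <- pa_covariates()
  # identical covariate rows in both groups: perfect symmetry, scores 0.5
  m_sym <- fit_propensity(X, X)
  expect_lt(max(abs(predict(m_sym, X) - 0.5)), 0.02)

  # a single strong covariate: score monotone in it
  tr <- X; tr$elevation <- tr$elevation + 2
  m1 <- fit_propensity(tr, X, covariates = "elevation")
  grid <- data.frame(elevation = seq(-3, 5, length.out = 50))
  expect_true(all(diff(predict(m1, grid)) > 0))

  # coefficients agree with an independent Newton iteration on the
  # explicit log-likelihood gradient and Hessian
  ls <- generate_landscape(tiny_config(seed = 1))
  pools <- build_control_pool(ls$cells, ls$pas, buffer_km = 5)
  model <- fit_propensity(pools$treated, pools$controls)
  Xs <- scale(as.matrix(rbind(pools$treated[, pa_covariates()],
                              pools$controls[, pa_covariates()])),
              center = model$centers, scale = model$scales)
  Xd <- cbind(1, Xs)
  y <- c(rep(1, nrow(pools$treated)), rep(0, nrow(pools$controls)))
  beta <- numeric(ncol(Xd))
  for (it in 1:60) {
    mu <- plogis(as.vector(Xd %*% beta))
    H <- crossprod(Xd, Xd * (mu * (1 - mu)))
    step <- solve(H, crossprod(Xd, y - mu))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  expect_equal(unname(model$coefficients), beta, tolerance = 1e-4)
})

test_that("perfect separation falls back to a ridge-penalized fit", {
  d <- data.frame(elevation = c(1:20))
  tr <- d[d$elevation > 10, , drop = FALSE]
  co <- d[d$elevation <= 10, , drop = FALSE]
  expect_warning(m <- fit_propensity(tr, co, covariates = "elevation"),
                 "separation")
  expect_identical(m$method, "ridge")
  expect_true(all(is.finite(m$coefficients)))
})

test_that("common support is the overlap interval and the caliper follows the SD rule", {
  fake <- list(range_treated = c(0.4, 0.9), range_control = c(0.1, 0.6),
               sd_logit = 0.5)
  cal <- set_caliper(fake)
  expect_equal(cal$support, c(0.4, 0.6))
  expect_equal(cal$caliper, 0.1)

  same <- list(range_treated = c(0.2, 0.8), range_control = c(0.2, 0.8),
               sd_logit = 1)
  expect_equal(set_caliper(same)$support, c(0.2, 0.8))

  apart <- list(range_treated = c(0.7, 0.9), range_control = c(0.1, 0.3),
                sd_logit = 1)
  expect_warning(c2 <- set_caliper(apart), "do not overlap")
  expect_true(all(is.na(c2$support)))
})

toy_match <- function(t_scores, c_scores, caliper,
                      c_country = NULL, rule = "nearest") {
  nt <- length(t_scores); ncn <- length(c_scores)
  treated <- manual_cells(data.frame(
    cell_id = seq_len(nt), is_protected = TRUE, pa_id = 1L,
    pa_cover_fraction = 1))
  treated$score_logit <- qlogis(t_scores)
  controls <- manual_cells(data.frame(cell_id = 100L + seq_len(ncn)))
  controls$score_logit <- qlogis(c_scores)
  if (!is.null(c_country)) controls$country <- c_country
  match_cells(treated, controls, identity_model(), caliper = caliper,
              match_rule = rule)
}

# brute force: enumerate all one-to-one assignments within the caliper and
# return the smallest achievable gap for a single treated cell
brute_best_gap <- function(t_score, c_scores, caliper) {
  gaps <- abs(c_scores - t_score)
  min(gaps[gaps <= caliper])
}

test_that("matching picks the nearest in-caliper control, without replacement", {
  mt <- toy_match(0.60, c(0.58, 0.70, 0.61), caliper = 0.05)
  expect_identical(nrow(mt$pairs), 1L)
  expect_identical(mt$pairs$control_cell_id, 103L)  # score 0.61, gap 0.01
  expect_equal(mt$pairs$abs_score_gap,
               brute_best_gap(0.60, c(0.58, 0.70, 0.61), 0.05),
               tolerance = 1e-12)

  # two treated, one control: one pair, the other treated unmatched
  mt2 <- toy_match(c(0.60, 0.59), 0.60, caliper = 0.05)
  expect_identical(nrow(mt2$pairs), 1L)
  expect_identical(mt2$pairs$pa_cell_id, 1L)  # higher score processed first
  expect_identical(mt2$unmatched$cell_id, 2L)

  # exact stratum: a control in another country is never paired
  mt3 <- toy_match(0.60, c(0.60, 0.59), caliper = 0.05,
                   c_country = c(2L, 1L))
  expect_identical(mt3$pairs$control_cell_id, 102L)

  # ties in gap break on the lowest control cell_id
  mt4 <- toy_match(0.60, c(0.61, 0.61), caliper = 0.05)
  expect_identical(mt4$pairs$control_cell_id, 101L)

  # max-score rule picks the highest-score eligible control
  mt5 <- toy_match(0.60, c(0.58, 0.61, 0.57), caliper = 0.05,
                   rule = "max_score")
  expect_identical(mt5$pairs$control_cell_id, 102L)
})

test_that("matched pairs satisfy injectivity, exact strata, caliper and support", {
  ls <- generate_landscape(tiny_config(seed = 4))
  fp <- filter_footprints(sample_footprints(ls))
  cm <- aggregate_to_cells(fp, ls$cells)
  pools <- build_control_pool(ls$cells, ls$pas, buffer_km = 5,
                              cell_metrics = cm)
  # separation is expected on such a small world; the ridge fallback applies
  model <- suppressWarnings(fit_propensity(pools$treated, pools$controls))
  cal <- set_caliper(model)
  mt <- match_cells(pools$treated, pools$controls, model, cal)
  p <- mt$pairs
  expect_gt(nrow(p), 10)
  expect_false(any(duplicated(p$pa_cell_id)))
  expect_false(any(duplicated(p$control_cell_id)))
  # exact stratum equality, field by field
  ctl <- pools$controls[match(p$control_cell_id, pools$controls$cell_id), ]
  for (v in c("land_cover", "country", "ecoregion", "biome")) {
    expect_identical(p[[v]], ctl[[v]])
  }
  expect_true(all(p$abs_score_gap <= mt$caliper + 1e-9))
  expect_true(all(p$score_pa >= mt$support[1] - 1e-9 &
                    p$score_pa <= mt$support[2] + 1e-9))
  expect_true(all(p$score_control >= mt$support[1] - 1e-9 &
                    p$score_control <= mt$support[2] + 1e-9))
  # every treated cell is accounted for
  expect_identical(nrow(p) + nrow(mt$unmatched), nrow(pools$treated))
})

test_that("balance reporting computes standardized mean differences", {
  set.seed(3)
  n <- 400
  tr <- manual_cells(data.frame(cell_id = 1:n))
  co <- manual_cells(data.frame(cell_id = n + 1:n))
  for (v in pa_covariates()) { tr[[v]] <- rnorm(n); co[[v]] <- rnorm(n) }
  tr$elevation <- tr$elevation + 1  # SMD 1 by construction
  pools <- list(treated = tr, controls = co)
  mt <- list(pairs = data.frame(pa_cell_id = 1:5, control_cell_id = n + 1:5,
                                score_pa = 0.5, score_control = 0.5))
  model <- identity_model()
  tr$score_logit <- 0; co$score_logit <- 0
  pools <- list(treated = tr, controls = co)
  bal <- balance_report(pools, mt, model)
  expect_equal(bal$smd_before[bal$covariate == "elevation"], 1,
               tolerance = 0.15)
  expect_equal(bal$smd_before[bal$covariate == "slope"], 0,
               tolerance = 0.2)
})
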