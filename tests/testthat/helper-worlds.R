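# shared synthetic worlds for the test suite

# small fast world for structural tests
tiny_config <- function(seed = 1, ...) {
  landscape_config(grid_rows = 40, grid_cols = 40, n_countries = 2,
                   n_biomes = 2, n_ecoregions = 2, n_landcovers = 2,
                   n_continents = 1, n_pas = 4, pa_min_cells = 5,
                   pa_max_cells = 12, seed = seed, ...)
}

# reduced replicate world for Monte-Carlo properties: large enough for a
# healthy control reservoir, small enough for hundreds of replicates
reduced_config <- function(seed = 1, ...) {
  landscape_config(grid_rows = 60, grid_cols = 60, n_countries = 2,
                   n_biomes = 2, n_ecoregions = 2, n_landcovers = 2,
                   n_continents = 1, n_pas = 6, pa_min_cells = 6,
                   pa_max_cells = 18, seed = seed, ...)
}

# minimal hand-built cell table for matching-geometry tests
manual_cells <- function(df) {
  defaults <- data.frame(
    cell_id = seq_len(nrow(df)), row = 1, col = 1, x = 0.5, y = 0.5,
    country = 1L, continent = 1L, biome = 1L, ecoregion = 1L,
    land_cover = 1L, elevation = 100, slope = 5, precip = 1000,
    tmin = 10, tmax = 20, dist_city = 10, dist_road = 5,
    travel_time = 30, pop_count = 10, pop_density = 10,
    is_protected = FALSE, pa_id = NA_integer_, pa_cover_fraction = 0,
    in_buffer = FALSE, loss_fraction = 0, baseline_agcd_2000 = 50
  )
  for (nm in names(df)) defaults[[nm]] <- df[[nm]]
  defaults
}

# propensity-model stub whose predictions equal a stored per-cell score
# (covariate "score_logit" carries the logit of the desired score)
identity_model <- function() {
  structure(list(
    coefficients = c(`(Intercept)` = 0, score_logit = 1),
    centers = c(score_logit = 0), scales = c(score_logit = 1),
    covariates = "score_logit", method = "irls",
    range_treated = c(0, 1), range_control = c(0, 1), sd_logit = 1
  ), class = "propensity_model")
}
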