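#' Configuration for the synthetic landscape generator
#'
#' Defines a self-contained synthetic world on a flat equal-area plane of
#' 1 km square cells: smooth covariate fields, confounded protected-area
#' (PA) placement, a known additive protection effect on aboveground biomass
#' density (AGBD), status-dependent forest-loss rates, and along-track lidar
#' footprint sampling. Because the generating parameters are known, every
#' downstream stage (filtering, matching, effect estimation, attribution)
#' can be verified by parameter recovery.
#'
#' @param grid_rows,grid_cols Grid dimensions in cells (1 cell = 1 km).
#' @param n_countries,n_biomes,n_ecoregions,n_landcovers,n_continents
#'   Category counts for the exact-matching covariates. Countries are
#'   contiguous vertical bands, biomes horizontal bands, ecoregions nested
#'   within biomes, land cover a spatially coherent discretisation of a
#'   smooth field; countries are grouped into continents.
#' @param n_pas Number of protected areas (connected cell patches grown
#'   from seeded locations, mutually disjoint with a small gap).
#' @param pa_effect_delta True additional AGBD from protection, Mg/ha. May
#'   be any real number; 0 gives a null world.
#' @param confounding_strength Dimensionless strength with which the
#'   covariate index that drives biomass also drives PA placement. 0 means
#'   randomised placement.
#' @param loss_rate_protected,loss_rate_unprotected Expected 2000-2019
#'   forest-cover-loss fraction per cell inside / outside PAs, in `[0, 1]`.
#' @param footprint_spacing_along_m Along-track shot spacing, metres.
#' @param track_spacing_m Spacing between parallel tracks, metres.
#' @param track_dropout_rate Fraction of along-track segments (of length
#'   `dropout_segment_km`) with no usable shots, emulating non-continuous
#'   lidar coverage; this is what produces cells with too few shots.
#' @param dropout_segment_km Length of a dropout segment, km.
#' @param shot_noise_sd Per-shot AGBD noise SD, Mg/ha (Gaussian, truncated
#'   at zero).
#' @param p_bad_quality Probability that a shot fails the quality flag.
#' @param sensitivity_shape1,sensitivity_shape2 Beta parameters of the
#'   per-shot sensitivity metric in `[0, 1]`.
#' @param pa_min_cells,pa_max_cells Range of PA patch sizes in cells
#'   (patches are grown cell-by-cell from a seed).
#' @param pa_gap_cells Minimum gap between distinct PA patches, cells.
#' @param status_year_range Range (inclusive) of PA designation years.
#' @param baseline_growth_rate Mg C/ha of extra year-2000 baseline carbon
#'   per year of pre-2000 protection; produces the older-PA baseline signal.
#' @param baseline_noise_sd SD of per-cell noise on the year-2000 baseline
#'   carbon map, Mg C/ha.
#' @param cell_noise_sd SD of per-cell biomass heterogeneity not captured
#'   by any covariate, Mg/ha (independent across cells).
#' @param seed Integer seed; the landscape is a deterministic function of
#'   the configuration including this seed.
#'
#' @return An object of class `landscape_config` (a validated list).
#' @export
landscape_config <- function(grid_rows = 100L, grid_cols = 100L,
                             n_countries = 3L, n_biomes = 3L,
                             n_ecoregions = 6L, n_landcovers = 3L,
                             n_continents = 2L,
                             n_pas = 20L,
                             pa_effect_delta = 10,
                             confounding_strength = 0.8,
                             loss_rate_protected = 0.01,
                             loss_rate_unprotected = 0.05,
                             footprint_spacing_along_m = 60,
                             track_spacing_m = 600,
                             track_dropout_rate = 0.3,
                             dropout_segment_km = 5,
                             shot_noise_sd = 25,
                             p_bad_quality = 0.1,
                             sensitivity_shape1 = 30,
                             sensitivity_shape2 = 1,
                             pa_min_cells = 8L,
                             pa_max_cells = 36L,
                             pa_gap_cells = 3L,
                             status_year_range = c(1940L, 2017L),
                             baseline_growth_rate = 0.15,
                             baseline_noise_sd = 5,
                             cell_noise_sd = 18,
                             seed = 1L) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    n_countries = as.integer(n_countries), n_biomes = as.integer(n_biomes),
    n_ecoregions = as.integer(n_ecoregions),
    n_landcovers = as.integer(n_landcovers),
    n_continents = as.integer(n_continents),
    n_pas = as.integer(n_pas),
    pa_effect_delta = pa_effect_delta,
    confounding_strength = confounding_strength,
    loss_rate_protected = loss_rate_protected,
    loss_rate_unprotected = loss_rate_unprotected,
    footprint_spacing_along_m = footprint_spacing_along_m,
    track_spacing_m = track_spacing_m,
    track_dropout_rate = track_dropout_rate,
    dropout_segment_km = dropout_segment_km,
    shot_noise_sd = shot_noise_sd,
    p_bad_quality = p_bad_quality,
    sensitivity_shape1 = sensitivity_shape1,
    sensitivity_shape2 = sensitivity_shape2,
    pa_min_cells = as.integer(pa_min_cells),
    pa_max_cells = as.integer(pa_max_cells),
    pa_gap_cells = as.integer(pa_gap_cells),
    status_year_range = as.integer(status_year_range),
    baseline_growth_rate = baseline_growth_rate,
    baseline_noise_sd = baseline_noise_sd,
    cell_noise_sd = cell_noise_sd,
    seed = as.integer(seed)
  )
  validate_landscape_config(cfg)
  structure(cfg, class = "landscape_config")
}

validate_landscape_config <- function(cfg) {
  counts <- c("grid_rows", "grid_cols", "n_countries", "n_biomes",
              "n_ecoregions", "n_landcovers", "n_continents", "n_pas")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
  }
  rates <- c("loss_rate_protected", "loss_rate_unprotected",
             "p_bad_quality", "track_dropout_rate")
  for (nm in rates) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  pos <- c("footprint_spacing_along_m", "track_spacing_m",
           "dropout_segment_km")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  nonneg <- c("shot_noise_sd", "baseline_noise_sd", "cell_noise_sd",
              "sensitivity_shape1", "sensitivity_shape2")
  for (nm in nonneg) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (!is.finite(cfg$pa_effect_delta))
    stop("'pa_effect_delta' must be finite", call. = FALSE)
  if (cfg$pa_min_cells < 1L || cfg$pa_max_cells < cfg$pa_min_cells)
    stop("PA patch sizes must satisfy 1 <= min <= max", call. = FALSE)
  # conservative feasibility bound: disjoint patches plus gaps must not
  # require more than ~60% of the grid, or placement cannot succeed
  footprint <- (ceiling(sqrt(cfg$pa_max_cells)) + 2L * cfg$pa_gap_cells)^2
  if (cfg$n_pas * footprint > 0.6 * cfg$grid_rows * cfg$grid_cols) {
    stop("grid too small to host n_pas protected areas with their gaps; ",
         "enlarge the grid or reduce n_pas / pa_max_cells",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.landscape_config <- function(x, ...) {
  cat(sprintf(
    "landscape_config: %d x %d km grid, %d PAs, delta = %g Mg/ha AGBD,\n",
    x$grid_rows, x$grid_cols, x$n_pas, x$pa_effect_delta))
  cat(sprintf(
    "  confounding = %g, loss in/out = %g/%g, shot noise SD = %g, seed = %d\n",
    x$confounding_strength, x$loss_rate_protected, x$loss_rate_unprotected,
    x$shot_noise_sd, x$seed))
  invisible(x)
}
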