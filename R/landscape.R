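# Synthetic landscape generation: smooth covariate fields, confounded PA
# placement by suitability-weighted region growing, known protection
# effect, loss fractions, year-2000 baseline.

# smooth standardized field over cell centers: sum of random plane waves
smooth_field <- function(x, y, n_harm = 10, length_scale = 30) {
  f <- numeric(length(x))
  for (k in seq_len(n_harm)) {
    theta <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 0.25, 1.5) / length_scale
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1) / k
    f <- f + amp * sin(2 * pi * freq * (cos(theta) * x + sin(theta) * y) + phase)
  }
  zstd(f)
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds the full synthetic world from a [landscape_config()]: a 1-km cell
#' table with smooth quantitative covariates (climate varying at broad
#' scales, terrain at intermediate and human pressure at fine scales) and
#' nested categorical labels; protected areas grown cell-by-cell from
#' seeded locations, preferring cells where the covariate index that also
#' drives biomass is high (so placement is confounded when
#' `confounding_strength > 0`, as when parks are gazetted over carbon-rich
#' land); per-cell expected AGBD with and without protection;
#' status-dependent forest-loss fractions; and a year-2000 baseline carbon
#' map in which pre-2000 protection has accrued extra growth.
#'
#' The expected AGBD of a cell is `baseline(covariates) + delta *
#' is_protected` where `delta = pa_effect_delta`; the per-cell truth table
#' is retained for tests and validation only and is never read by the
#' analysis stages.
#'
#' @param config A [landscape_config()].
#' @return An object of class `pacarbon_landscape`: a list with elements
#'   `cells` (one row per 1-km cell), `pas` (one row per protected area),
#'   `truth` (per-cell expected AGBD with and without protection),
#'   `true_delta`, and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  validate_landscape_config(config)
  set.seed(config$seed)

  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  x <- col - 0.5; y <- row - 0.5
  cell_id <- seq_len(n)

  # spatial scales: climate broader than terrain, terrain broader than
  # human pressure, but all decorrelating well within the grid and within
  # the matching buffer scale, so (a) counterfactual cells beyond the
  # buffer exist for every PA cell and (b) a handful of PA patches samples
  # many independent field values rather than one value per patch
  ls_clim <- max(4, min(nr, nc) / 22)
  ls_terr <- max(3.5, min(nr, nc) / 26)
  ls_pres <- max(3, min(nr, nc) / 33)

  f_elev <- smooth_field(x, y, length_scale = ls_terr)
  f_slope <- smooth_field(x, y, length_scale = ls_pres)
  f_precip <- smooth_field(x, y, length_scale = ls_clim)
  f_temp <- smooth_field(x, y, length_scale = ls_clim)
  f_city <- smooth_field(x, y, length_scale = ls_terr)
  f_road <- smooth_field(x, y, length_scale = ls_pres)
  f_acc <- smooth_field(x, y, length_scale = ls_pres)
  f_pop <- smooth_field(x, y, length_scale = ls_pres)
  f_lc <- smooth_field(x, y, length_scale = ls_terr)

  elevation <- pmax(0, 800 + 600 * f_elev)
  slope <- pmin(45, pmax(0, 8 + 6 * f_slope))
  precip <- pmax(100, 1500 + 700 * f_precip)
  tmin <- 12 + 6 * f_temp
  tmax <- tmin + 8 + 3 * abs(smooth_field(x, y, length_scale = ls_clim))
  dist_city <- pmax(0, 60 + 40 * f_city)
  dist_road <- pmax(0, 15 + 10 * f_road)
  travel_time <- pmax(5, 30 + 3 * dist_city + 60 * abs(f_acc))
  pop_density <- exp(2 - 1.2 * f_city + 0.8 * f_pop)
  pop_count <- pop_density * exp(stats::rnorm(n, 0, 0.1))

  # categorical labels: countries as vertical bands, biomes horizontal,
  # ecoregions nested in biomes, land cover from a coherent smooth field
  country <- pmin(config$n_countries,
                  1L + as.integer((col - 1L) * config$n_countries / nc))
  biome <- pmin(config$n_biomes,
                1L + as.integer((row - 1L) * config$n_biomes / nr))
  per_cont <- ceiling(config$n_countries / config$n_continents)
  continent <- pmin(config$n_continents, 1L + (country - 1L) %/% per_cont)
  eco_per_biome <- max(1L, ceiling(config$n_ecoregions / config$n_biomes))
  eco_sub <- pmin(eco_per_biome,
                  1L + as.integer((col - 1L) * eco_per_biome / nc))
  ecoregion <- (biome - 1L) * eco_per_biome + eco_sub
  lc_breaks <- stats::quantile(f_lc, probs = seq(0, 1,
                                                 length.out = config$n_landcovers + 1L))
  lc_breaks[1] <- -Inf; lc_breaks[length(lc_breaks)] <- Inf
  land_cover <- as.integer(cut(f_lc, breaks = lc_breaks, labels = FALSE))

  # biomass-driving covariate index, dominated by the finer-scale
  # pressure/terrain covariates; also drives PA placement (confounding)
  z_cov <- zstd(-0.75 * zstd(log1p(pop_density)) +
                  0.45 * zstd(precip) + 0.45 * zstd(elevation) -
                  0.45 * zstd(travel_time) + 0.3 * zstd(slope) +
                  0.25 * zstd(dist_road) + 0.25 * zstd(tmin))
  eps_cell <- stats::rnorm(n, 0, config$cell_noise_sd)
  agbd_untreated <- pmax(5, 160 + 35 * z_cov + eps_cell)
  agbd_treated <- agbd_untreated + config$pa_effect_delta

  pa_of_cell <- grow_pas(config, z_cov, row, col, nr, nc)
  is_protected <- !is.na(pa_of_cell)
  pas <- data.frame(pa_id = sort(unique(pa_of_cell[is_protected])))

  # status-dependent forest loss fractions (Beta around the expected rate)
  rate <- ifelse(is_protected, config$loss_rate_protected,
                 config$loss_rate_unprotected)
  conc <- 8
  loss_fraction <- ifelse(rate <= 0, 0, ifelse(rate >= 1, 1, NA_real_))
  need <- is.na(loss_fraction)
  if (any(need)) {
    loss_fraction[need] <- stats::rbeta(sum(need), rate[need] * conc,
                                        (1 - rate[need]) * conc)
  }

  # PA attributes derived from member cells
  pa_rows <- lapply(pas$pa_id, function(id) which(pa_of_cell == id))
  pas$area_km2 <- vapply(pa_rows, length, integer(1))
  pas$country <- vapply(pa_rows, function(ix) as.integer(names(which.max(table(country[ix])))), integer(1))
  pas$continent <- continent[match(pas$country, country)]
  pas$biome <- vapply(pa_rows, function(ix) as.integer(names(which.max(table(biome[ix])))), integer(1))
  pas$forest_flag <- vapply(pa_rows, function(ix) {
    mean(land_cover[ix] <= ceiling(config$n_landcovers / 2)) >= 0.5
  }, logical(1))
  pas$status_yr <- sample(seq(config$status_year_range[1],
                              config$status_year_range[2]), nrow(pas),
                          replace = TRUE)

  # year-2000 baseline carbon: pre-2000 protection has accrued growth
  age_2000 <- pmax(0, 2000 - pas$status_yr[match(pa_of_cell, pas$pa_id)])
  age_2000[is.na(age_2000)] <- 0
  baseline_agcd_2000 <- pmax(0, 0.49 * agbd_untreated +
                               config$baseline_growth_rate * age_2000 +
                               stats::rnorm(n, 0, config$baseline_noise_sd))

  cells <- data.frame(
    cell_id = cell_id, row = row, col = col, x = x, y = y,
    country = country, continent = continent, biome = biome,
    ecoregion = ecoregion, land_cover = land_cover,
    elevation = elevation, slope = slope, precip = precip,
    tmin = tmin, tmax = tmax, dist_city = dist_city, dist_road = dist_road,
    travel_time = travel_time, pop_count = pop_count,
    pop_density = pop_density,
    is_protected = is_protected, pa_id = pa_of_cell,
    pa_cover_fraction = ifelse(is_protected, 1, 0),
    in_buffer = FALSE,
    loss_fraction = loss_fraction,
    baseline_agcd_2000 = baseline_agcd_2000
  )
  truth <- data.frame(
    cell_id = cell_id,
    agbd_untreated = agbd_untreated,
    agbd_treated = agbd_treated,
    agbd_expected = ifelse(is_protected, agbd_treated, agbd_untreated)
  )
  structure(list(cells = cells, pas = pas, truth = truth,
                 true_delta = config$pa_effect_delta, config = config),
            class = "pacarbon_landscape")
}

# Grow n_pas connected PA patches. Seeds are drawn with probability
# proportional to a logistic function of the confounded suitability index;
# each patch then grows cell-by-cell, drawing the next member from its
# frontier with the same suitability weighting, so individual cells are
# selected on their own covariates (parks follow carbon-rich terrain).
# Patches keep a minimum gap from each other.
grow_pas <- function(config, z_cov, row, col, nr, nc) {
  gap <- config$pa_gap_cells
  weight <- stats::plogis(config$confounding_strength * z_cov)
  pa_of_cell <- rep(NA_integer_, nr * nc)
  blocked <- rep(FALSE, nr * nc)  # patch cells + inter-patch gaps
  idx <- function(r, c) (r - 1L) * nc + c

  sizes <- sample(seq(config$pa_min_cells, config$pa_max_cells),
                  config$n_pas, replace = TRUE)
  attempts <- 0L
  max_attempts <- 200L * config$n_pas
  placed <- 0L
  while (placed < config$n_pas) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("grid too small to host n_pas protected areas with their gaps: ",
           "placement failed after ", max_attempts, " attempts",
           call. = FALSE)
    }
    free <- !blocked
    if (!any(free)) {
      stop("grid too small to host n_pas protected areas with their gaps: ",
           "no free cells left", call. = FALSE)
    }
    seed <- sample.int(length(z_cov), 1L, prob = weight * free)
    target <- sizes[placed + 1L]
    members <- seed
    repeat {
      if (length(members) >= target) break
      # frontier: unblocked 4-neighbours of current members
      r <- row[members]; c <- col[members]
      cand <- unique(c(
        idx(pmax(r - 1L, 1L), c), idx(pmin(r + 1L, nr), c),
        idx(r, pmax(c - 1L, 1L)), idx(r, pmin(c + 1L, nc))
      ))
      cand <- setdiff(cand[!blocked[cand]], members)
      if (length(cand) == 0) break
      nxt <- if (length(cand) == 1) cand else {
        sample(cand, 1L, prob = weight[cand])
      }
      members <- c(members, nxt)
    }
    if (length(members) < config$pa_min_cells) next
    placed <- placed + 1L
    pa_of_cell[members] <- placed
    # block members and a gap ring around them
    for (dr in -gap:gap) for (dc in -gap:gap) {
      rr <- row[members] + dr; cc <- col[members] + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      blocked[idx(rr[ok], cc[ok])] <- TRUE
    }
  }
  pa_of_cell
}

#' @export
print.pacarbon_landscape <- function(x, ...) {
  cat(sprintf("pacarbon_landscape: %d cells (%d x %d km), %d PAs (%d protected cells), true delta = %g Mg/ha\n",
              nrow(x$cells), x$config$grid_rows, x$config$grid_cols,
              nrow(x$pas), sum(x$cells$is_protected), x$true_delta))
  invisible(x)
}
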