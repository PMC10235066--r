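# Effect estimation: paired carbon differences by stratum, hybrid
# sampling+model variance, area expansion to totals, extrapolation for
# unmatched PAs, and multi-scale aggregation with uncertainty.

#' Dissolved (non-overlapping) protected area
#'
#' Overlapping protected areas are counted once: the dissolved total is the
#' size of the union of all PA cell sets, and each PA's exclusive area
#' excludes cells already attributed to an earlier-listed PA (stable order
#' by `pa_id`).
#'
#' @param pa_cells Data frame with columns `pa_id` and `cell_id`, one row
#'   per (PA, member cell); cell areas are 1 km2.
#' @return List with `per_pa` (`pa_id`, `area_km2_raw`,
#'   `area_km2_exclusive`) and `total_km2` (dissolved union area).
#' @export
dissolve_pa_area <- function(pa_cells) {
  stopifnot_cols(pa_cells, c("pa_id", "cell_id"), "PA-cell table")
  ids <- sort(unique(pa_cells$pa_id))
  seen <- integer(0)
  per_pa <- data.frame(pa_id = ids, area_km2_raw = NA_real_,
                       area_km2_exclusive = NA_real_)
  for (i in seq_along(ids)) {
    cells_i <- unique(pa_cells$cell_id[pa_cells$pa_id == ids[i]])
    per_pa$area_km2_raw[i] <- length(cells_i)
    new_i <- setdiff(cells_i, seen)
    per_pa$area_km2_exclusive[i] <- length(new_i)
    seen <- c(seen, new_i)
  }
  list(per_pa = per_pa, total_km2 = length(seen))
}

#' Hybrid mean and standard error for a set of cell means
#'
#' Mean carbon density over 1-km cell means with a variance that combines
#' the sampling variance of the mean (`s^2/n` over cell means, reflecting
#' the lidar sampling design) and a relative model-error term
#' `(model_rel_se * mean)^2` standing in for footprint biomass-model
#' parameter error. The two components add on the variance scale.
#'
#' @param cell_means Numeric vector of qualified cell means (Mg C/ha).
#' @param model_rel_se Relative SE of the biomass model contribution
#'   (default 0.02).
#' @return List with `mean`, `se`, `n`, `var_sampling`, `var_model`,
#'   `low_confidence` (`TRUE` when `n < 2`, in which case `se` is `NA`).
#' @export
hybrid_mean_se <- function(cell_means, model_rel_se = 0.02) {
  cell_means <- cell_means[!is.na(cell_means)]
  n <- length(cell_means)
  if (n == 0) {
    return(list(mean = NA_real_, se = NA_real_, n = 0L,
                var_sampling = NA_real_, var_model = NA_real_,
                low_confidence = TRUE))
  }
  m <- mean(cell_means)
  if (n < 2) {
    return(list(mean = m, se = NA_real_, n = n,
                var_sampling = NA_real_, var_model = (model_rel_se * m)^2,
                low_confidence = TRUE))
  }
  vs <- stats::var(cell_means) / n
  vm <- (model_rel_se * m)^2
  list(mean = m, se = sqrt(vs + vm), n = n,
       var_sampling = vs, var_model = vm, low_confidence = FALSE)
}

#' Paired carbon differences by stratum
#'
#' For each matched pair, the difference is the PA cell's mean carbon
#' density minus its matched control's. Differences are grouped by the
#' requested stratum key and summarised with the paired-difference standard
#' error `sd(d)/sqrt(n)`. Structural-metric differences (AGBD, RH98,
#' canopy cover, PAI) are carried along.
#'
#' @param pairs Pair table from [match_cells()] (`$pairs`).
#' @param cell_metrics Output of [aggregate_to_cells()].
#' @param by Character vector of grouping columns on the pair table (e.g.
#'   `"pa_id"`, `c("country", "biome")`), or `"globe"` for a single
#'   all-pairs stratum.
#' @return Data frame with one row per stratum: the key columns,
#'   `n_pairs`, group means of both sides, `mean_diff` and `se_diff`
#'   (Mg C/ha; `se_diff` is `NA` and `low_confidence` `TRUE` when
#'   `n_pairs < 2`), plus `mean_diff_agbd`, `mean_diff_rh98`,
#'   `mean_diff_cover`, `mean_diff_pai`.
#' @export
stratum_difference <- function(pairs, cell_metrics, by = "pa_id") {
  if (nrow(pairs) == 0) return(data.frame())
  it <- match(pairs$pa_cell_id, cell_metrics$cell_id)
  ic <- match(pairs$control_cell_id, cell_metrics$cell_id)
  d <- data.frame(
    agcd_pa = cell_metrics$mean_agcd[it],
    agcd_control = cell_metrics$mean_agcd[ic],
    d_agcd = cell_metrics$mean_agcd[it] - cell_metrics$mean_agcd[ic],
    d_agbd = cell_metrics$mean_agbd[it] - cell_metrics$mean_agbd[ic],
    d_rh98 = cell_metrics$mean_rh98[it] - cell_metrics$mean_rh98[ic],
    d_cover = cell_metrics$mean_cover[it] - cell_metrics$mean_cover[ic],
    d_pai = cell_metrics$mean_pai[it] - cell_metrics$mean_pai[ic]
  )
  if (identical(by, "globe")) {
    key <- data.frame(stratum = rep("globe", nrow(pairs)))
    by <- "stratum"
  } else {
    stopifnot_cols(pairs, by, "pair table")
    key <- pairs[, by, drop = FALSE]
  }
  groups <- split(seq_len(nrow(d)), key, drop = TRUE)
  rows <- lapply(groups, function(ix) {
    n <- length(ix)
    se <- if (n >= 2) stats::sd(d$d_agcd[ix]) / sqrt(n) else NA_real_
    cbind(
      key[ix[1], , drop = FALSE],
      data.frame(
        n_pairs = n,
        mean_agcd_pa = mean(d$agcd_pa[ix]),
        mean_agcd_control = mean(d$agcd_control[ix]),
        mean_diff = mean(d$d_agcd[ix]),
        se_diff = se,
        low_confidence = n < 2,
        mean_diff_agbd = mean(d$d_agbd[ix]),
        mean_diff_rh98 = mean(d$d_rh98[ix]),
        mean_diff_cover = mean(d$d_cover[ix]),
        mean_diff_pai = mean(d$d_pai[ix])
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand a per-area density to a total stock
#'
#' Converts Mg C/ha over an area in km2 to Gt: `total_Gt =
#' mean * area_km2 * 100 * 1e-9` (100 ha per km2, 1e9 Mg per Gt). The
#' standard error scales identically. Vectorized.
#'
#' @param mean,se Density and its SE, Mg C/ha.
#' @param area_km2 Area, km2, `>= 0`.
#' @return Data frame with `total_gt`, `se_gt`.
#' @export
expand_to_total <- function(mean, se, area_km2) {
  if (any(!is.na(area_km2) & area_km2 < 0)) {
    stop("area must be non-negative", call. = FALSE)
  }
  f <- area_km2 * 100 * 1e-9
  data.frame(total_gt = mean * f, se_gt = se * f)
}

#' Fill in unmatched PAs from stratum-level results
#'
#' PAs without matched estimates inherit the country-by-biome mean
#' difference (and mean PA carbon density); where that stratum is absent,
#' the continent-by-biome result is used; where both are absent the PA is
#' flagged `no_estimate` and excluded from totals (but counted in
#' coverage).
#'
#' @param pas PA table with `pa_id`, `country`, `continent`, `biome`.
#' @param cb Country-by-biome table from [stratum_difference()].
#' @param contb Continent-by-biome table from [stratum_difference()].
#' @return Data frame `pa_id`, `mean_diff`, `se_diff`, `mean_agcd_pa`,
#'   `provenance`.
#' @export
extrapolate_unmatched <- function(pas, cb, contb) {
  k_cb <- if (nrow(cb)) paste(cb$country, cb$biome) else character(0)
  k_ctb <- if (nrow(contb)) paste(contb$continent, contb$biome) else character(0)
  i_cb <- match(paste(pas$country, pas$biome), k_cb)
  i_ctb <- match(paste(pas$continent, pas$biome), k_ctb)
  use_cb <- !is.na(i_cb)
  use_ctb <- !use_cb & !is.na(i_ctb)
  out <- data.frame(
    pa_id = pas$pa_id,
    mean_diff = NA_real_, se_diff = NA_real_, mean_agcd_pa = NA_real_,
    provenance = ifelse(use_cb, "extrapolated_country_biome",
                        ifelse(use_ctb, "extrapolated_continent_biome",
                               "no_estimate"))
  )
  out$mean_diff[use_cb] <- cb$mean_diff[i_cb[use_cb]]
  out$se_diff[use_cb] <- cb$se_diff[i_cb[use_cb]]
  out$mean_agcd_pa[use_cb] <- cb$mean_agcd_pa[i_cb[use_cb]]
  out$mean_diff[use_ctb] <- contb$mean_diff[i_ctb[use_ctb]]
  out$se_diff[use_ctb] <- contb$se_diff[i_ctb[use_ctb]]
  out$mean_agcd_pa[use_ctb] <- contb$mean_agcd_pa[i_ctb[use_ctb]]
  out
}

#' Aggregate per-PA estimates to a coarser scale
#'
#' Totals are sums; variances are summed assuming independence across
#' strata (so the SE of the sum is the root of the summed squared SEs);
#' areas are sums of exclusive (dissolved) areas.
#'
#' @param pa_table Per-PA estimate table with at least `additional_gt`;
#'   optionally `se_additional_gt`, `total_agc_gt`, `se_total_agc_gt`,
#'   `area_km2`, `n_pairs`.
#' @param level `"globe"` or the name of a grouping column on `pa_table`
#'   (`"country"`, `"continent"`, `"biome"`).
#' @return One row per group with summed totals and combined SEs.
#' @export
aggregate_estimates <- function(pa_table, level = "globe") {
  stopifnot_cols(pa_table, "additional_gt", "estimate table")
  if (identical(level, "globe")) {
    key <- rep("globe", nrow(pa_table))
  } else {
    stopifnot_cols(pa_table, level, "estimate table")
    key <- pa_table[[level]]
  }
  sum0 <- function(v) sum(v, na.rm = TRUE)
  rss <- function(v) sqrt(sum(v^2, na.rm = TRUE))
  opt <- function(g, col, f) {
    if (col %in% names(pa_table)) f(pa_table[[col]][g]) else NA_real_
  }
  groups <- split(seq_len(nrow(pa_table)), key, drop = TRUE)
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    data.frame(
      group = nm,
      n_pas = length(g),
      n_pairs = opt(g, "n_pairs", sum0),
      additional_gt = sum0(pa_table$additional_gt[g]),
      se_additional_gt = opt(g, "se_additional_gt", rss),
      total_agc_gt = opt(g, "total_agc_gt", sum0),
      se_total_agc_gt = opt(g, "se_total_agc_gt", rss),
      area_km2 = opt(g, "area_km2", sum0)
    )
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- if (identical(level, "globe")) "level" else level
  rownames(out) <- NULL
  out
}

#' Full effect-estimation stage
#'
#' The mean carbon difference and its standard error are computed at the
#' country-by-biome scale from the matched pairs and expanded by the
#' (dissolved) PA area of each stratum; strata whose PAs have no matched
#' pairs inherit the continent-by-biome result (extrapolation), and strata
#' with neither contribute area only to a coverage report. Totals at
#' country, continent, biome and global scale are sums over strata, with
#' SEs combined as independent. A per-PA table (own-pair differences where
#' available, with provenance) is kept for PA-level reporting and the
#' effectiveness classification; total PA carbon stocks use the hybrid
#' estimator over each stratum's qualified protected cells.
#'
#' @param match Output of [match_cells()].
#' @param cell_metrics Output of [aggregate_to_cells()].
#' @param cells Cell table.
#' @param pas PA table.
#' @param model_rel_se Relative model-error term for [hybrid_mean_se()].
#' @return List with `pa_table`, `stratum_table` (one row per
#'   country-by-biome stratum with area, additional carbon and stock
#'   totals), `country_biome`, `continent_biome`, `globe_pairs` (all-pairs
#'   paired difference), `by_country`, `by_continent`, `by_biome`,
#'   `globe`, `coverage` (strata/PAs without any estimate), `areas`, and
#'   `naive_diff` (the unmatched protected-minus-unprotected difference,
#'   for comparison).
#' @export
estimate_effects <- function(match, cell_metrics, cells, pas,
                             model_rel_se = 0.02) {
  pairs <- match$pairs
  pa_diff <- stratum_difference(pairs, cell_metrics, by = "pa_id")
  cb <- stratum_difference(pairs, cell_metrics, by = c("country", "biome"))
  contb <- stratum_difference(pairs, cell_metrics,
                              by = c("continent", "biome"))
  globe_pairs <- stratum_difference(pairs, cell_metrics, by = "globe")

  pc <- cells[cells$is_protected, c("pa_id", "cell_id")]
  areas <- dissolve_pa_area(pc)

  pa_table <- pas[, intersect(c("pa_id", "country", "continent", "biome",
                                "status_yr", "forest_flag"), names(pas))]
  ai <- match(pa_table$pa_id, areas$per_pa$pa_id)
  pa_table$area_km2 <- areas$per_pa$area_km2_exclusive[ai]

  mi <- match(pa_table$pa_id, pa_diff$pa_id)
  pa_table$n_pairs <- ifelse(is.na(mi), 0L, pa_diff$n_pairs[mi])
  pa_table$mean_diff <- pa_diff$mean_diff[mi]
  pa_table$se_diff <- pa_diff$se_diff[mi]
  pa_table$mean_diff_agbd <- pa_diff$mean_diff_agbd[mi]
  pa_table$provenance <- ifelse(!is.na(mi), "matched", NA_character_)
  need <- is.na(mi)
  if (any(need)) {
    ext <- extrapolate_unmatched(pa_table[need, , drop = FALSE], cb, contb)
    pa_table$provenance[need] <- ext$provenance
  }

  # stratum table: every country-by-biome stratum holding PA area
  st <- stats::aggregate(area_km2 ~ country + biome,
                         data = pa_table, FUN = sum)
  st$continent <- pas$continent[match(st$country, pas$country)]
  i_cb <- match(paste(st$country, st$biome), paste(cb$country, cb$biome))
  i_ctb <- match(paste(st$continent, st$biome),
                 paste(contb$continent, contb$biome))
  use_cb <- !is.na(i_cb)
  use_ctb <- !use_cb & !is.na(i_ctb)
  st$provenance <- ifelse(use_cb, "matched",
                          ifelse(use_ctb, "extrapolated_continent_biome",
                                 "no_estimate"))
  pick <- function(col) {
    out <- rep(NA_real_, nrow(st))
    out[use_cb] <- cb[[col]][i_cb[use_cb]]
    out[use_ctb] <- contb[[col]][i_ctb[use_ctb]]
    out
  }
  st$n_pairs <- ifelse(use_cb, cb$n_pairs[i_cb], 0L)
  st$mean_diff <- pick("mean_diff")
  st$se_diff <- pick("se_diff")

  # total stock: hybrid estimator over the stratum's qualified PA cells
  pa_of <- pa_table[match(pc$pa_id, pa_table$pa_id), c("country", "biome")]
  mm <- cell_metrics$mean_agcd[match(pc$cell_id, cell_metrics$cell_id)]
  skey <- paste(pa_of$country, pa_of$biome)
  st$mean_agcd <- NA_real_; st$se_agcd <- NA_real_
  for (i in seq_len(nrow(st))) {
    h <- hybrid_mean_se(mm[skey == paste(st$country[i], st$biome[i])],
                        model_rel_se)
    st$mean_agcd[i] <- h$mean; st$se_agcd[i] <- h$se
  }
  miss_stock <- is.na(st$mean_agcd)
  st$mean_agcd[miss_stock] <- pick("mean_agcd_pa")[miss_stock]

  est <- st$provenance != "no_estimate"
  add <- expand_to_total(st$mean_diff, st$se_diff, st$area_km2)
  tot <- expand_to_total(st$mean_agcd, st$se_agcd, st$area_km2)
  st$additional_gt <- ifelse(est, add$total_gt, NA_real_)
  st$se_additional_gt <- ifelse(est, add$se_gt, NA_real_)
  st$total_agc_gt <- tot$total_gt
  st$se_total_agc_gt <- tot$se_gt

  coverage <- list(
    n_strata = nrow(st), n_strata_estimated = sum(est),
    area_km2_estimated = sum(st$area_km2[est]),
    area_km2_no_estimate = sum(st$area_km2[!est])
  )
  st_est <- st[est, , drop = FALSE]

  list(
    pa_table = pa_table,
    stratum_table = st,
    country_biome = cb,
    continent_biome = contb,
    globe_pairs = globe_pairs,
    by_country = aggregate_estimates(st_est, "country"),
    by_continent = aggregate_estimates(st_est, "continent"),
    by_biome = aggregate_estimates(st_est, "biome"),
    globe = aggregate_estimates(st_est, "globe"),
    coverage = coverage,
    areas = areas,
    naive_diff = naive_difference(cell_metrics, cells)
  )
}

#' Naive (unmatched) protected-minus-unprotected difference
#'
#' Difference of mean carbon density between all qualified protected cells
#' and all qualified unprotected cells, with no matching, buffering or
#' stratification. On a confounded landscape this is biased; it is
#' reported only as the comparison point for the matched estimate.
#'
#' @param cell_metrics Output of [aggregate_to_cells()].
#' @param cells Cell table.
#' @return List with `diff` (Mg C/ha), `mean_protected`,
#'   `mean_unprotected`.
#' @export
naive_difference <- function(cell_metrics, cells) {
  m <- cell_metrics[match(cells$cell_id, cell_metrics$cell_id), ]
  q <- m$qualified & !is.na(m$mean_agcd)
  mp <- mean(m$mean_agcd[q & cells$is_protected])
  mu <- mean(m$mean_agcd[q & !cells$is_protected])
  list(diff = mp - mu, mean_protected = mp, mean_unprotected = mu)
}
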