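# Preferential-placement check: year-2000 baseline carbon differences
# between PA and matched cells, and their regression on PA age.

#' Per-PA baseline (year-2000) carbon differences
#'
#' For each matched pair, the baseline difference is the PA cell's
#' year-2000 carbon density minus its matched control's; per-PA means are
#' reported with the PA's status year, age relative to the 2000 baseline
#' (`2000 - status_yr`, negative for post-2000 designations), and
#' forest/non-forest flag. PAs whose cells lack baseline values are
#' excluded.
#'
#' @param pairs Pair table from [match_cells()] (`$pairs`).
#' @param cells Cell table with `baseline_agcd_2000`.
#' @param pas PA table with `status_yr` and `forest_flag`.
#' @return Data frame: `pa_id`, `status_year`, `pa_age_years`,
#'   `baseline_diff` (Mg C/ha), `forest_flag`, `n_pairs`, `group`
#'   (`"recent"` for status year >= 2000, else `"older"`).
#' @export
baseline_differences <- function(pairs, cells, pas) {
  if (nrow(pairs) == 0) return(data.frame())
  stopifnot_cols(cells, "baseline_agcd_2000", "cell table")
  bt <- cells$baseline_agcd_2000[match(pairs$pa_cell_id, cells$cell_id)]
  bc <- cells$baseline_agcd_2000[match(pairs$control_cell_id, cells$cell_id)]
  d <- bt - bc
  keep <- !is.na(d)
  groups <- split(which(keep), pairs$pa_id[keep], drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    ix <- groups[[nm]]
    data.frame(pa_id = type.convert(nm, as.is = TRUE),
               baseline_diff = mean(d[ix]), n_pairs = length(ix))
  }))
  pi <- match(out$pa_id, pas$pa_id)
  out$status_year <- pas$status_yr[pi]
  out$pa_age_years <- 2000 - out$status_year
  out$forest_flag <- pas$forest_flag[pi]
  out$group <- ifelse(out$status_year >= 2000, "recent", "older")
  rownames(out) <- NULL
  out[, c("pa_id", "status_year", "pa_age_years", "baseline_diff",
          "forest_flag", "n_pairs", "group")]
}

#' Recent-versus-older baseline contrast
#'
#' Group means of the per-PA baseline differences for recently established
#' PAs (status year >= 2000) versus older PAs, and the ratio of the two
#' group means.
#'
#' @param records Output of [baseline_differences()].
#' @return List with the per-group summary data frame and
#'   `recent_to_older_ratio` (of group mean differences; `NA` when a group
#'   is empty or the older mean is 0).
#' @export
baseline_group_summary <- function(records) {
  groups <- split(records$baseline_diff, records$group)
  tab <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    data.frame(group = nm, n = length(v), mean_diff = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  ratio <- NA_real_
  if (all(c("recent", "older") %in% tab$group)) {
    mo <- tab$mean_diff[tab$group == "older"]
    if (is.finite(mo) && mo != 0) {
      ratio <- tab$mean_diff[tab$group == "recent"] / mo
    }
  }
  list(by_group = tab, recent_to_older_ratio = ratio)
}

#' Regress baseline differences on PA age
#'
#' Ordinary least squares of the per-PA baseline carbon difference on PA
#' age, computed from the normal equations, with the standard t-test on
#' the slope. Optionally run separately for forest and non-forest PAs.
#'
#' @param records Output of [baseline_differences()].
#' @param by_forest Also fit within forest / non-forest strata.
#' @return List with `slope` (Mg C/ha per year), `intercept`, `se_slope`,
#'   `t_value`, `p_value`, `r` (Pearson correlation), `n`. With
#'   `by_forest = TRUE`, a list of such fits (`all`, `forest`,
#'   `nonforest`; strata with fewer than 3 distinct ages are `NULL`).
#' @export
age_regression <- function(records, by_forest = FALSE) {
  fit1 <- function(rec) {
    x <- rec$pa_age_years; y <- rec$baseline_diff
    if (length(unique(x)) < 2) {
      stop("degenerate design: PA age is constant", call. = FALSE)
    }
    if (length(x) < 3) {
      stop("need at least 3 records for the age regression", call. = FALSE)
    }
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    rss <- sum((y - intercept - slope * x)^2)
    se_slope <- sqrt(rss / (n - 2) / sxx)
    t_value <- slope / se_slope
    list(slope = slope, intercept = intercept, se_slope = se_slope,
         t_value = t_value,
         p_value = 2 * stats::pt(-abs(t_value), df = n - 2),
         r = stats::cor(x, y), n = n)
  }
  if (!by_forest) return(fit1(records))
  safe <- function(rec) {
    if (nrow(rec) < 3 || length(unique(rec$pa_age_years)) < 2) return(NULL)
    fit1(rec)
  }
  list(all = fit1(records),
       forest = safe(records[records$forest_flag, , drop = FALSE]),
       nonforest = safe(records[!records$forest_flag, , drop = FALSE]))
}
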