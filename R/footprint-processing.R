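# Footprint quality filtering, biomass-to-carbon conversion, and
# aggregation of shots to 1-km cell means.

#' Quality-filter lidar footprints
#'
#' Retains exactly the shots with `quality_flag == 1` and `sensitivity`
#' at or above the threshold (the threshold is inclusive). Order-preserving;
#' the input is not modified.
#'
#' @param shots Footprint table with at least `quality_flag` and
#'   `sensitivity` columns.
#' @param sensitivity_threshold Minimum sensitivity, default 0.95.
#' @return The retained subset of `shots`.
#' @export
filter_footprints <- function(shots, sensitivity_threshold = 0.95) {
  stopifnot_cols(shots, c("quality_flag", "sensitivity"), "footprint table")
  shots[shots$quality_flag == 1 & shots$sensitivity >= sensitivity_threshold, ,
        drop = FALSE]
}

#' Convert aboveground biomass density to carbon density
#'
#' Multiplies AGBD (Mg/ha) by the dry-woody-biomass carbon fraction
#' (default 0.49, the IPCC global average) to obtain AGCD (Mg C/ha).
#' Linear and elementwise.
#'
#' @param agbd Numeric vector of AGBD values, Mg/ha, all `>= 0`.
#' @param carbon_factor Carbon fraction of dry biomass.
#' @return AGCD values, Mg C/ha.
#' @export
agbd_to_agcd <- function(agbd, carbon_factor = 0.49) {
  if (any(!is.na(agbd) & agbd < 0)) {
    stop("AGBD must be non-negative", call. = FALSE)
  }
  carbon_factor * agbd
}

#' Aggregate quality-filtered shots to 1-km cell means
#'
#' Computes unweighted arithmetic means of each structural metric (RH98,
#' canopy cover, PAI, AGBD) over the passing shots of each cell, converts
#' the AGBD mean to carbon, and flags cells with fewer than `min_shots`
#' passing shots as unqualified (their means are `NA` and they are excluded
#' from matching). Every cell in `cells` gets a row, including cells with
#' no shots.
#'
#' @param shots Quality-filtered footprint table ([filter_footprints()]).
#' @param cells Cell table (only `cell_id` is used).
#' @param min_shots Minimum passing shots for a cell to qualify, default 5.
#' @param shots_unfiltered Optional unfiltered shot table, used to report
#'   `n_shots_total` for diagnostics; defaults to the filtered counts.
#' @param carbon_factor Carbon fraction for the AGCD mean.
#' @return Data frame with one row per cell: `cell_id`, `n_shots_total`,
#'   `n_shots_pass`, `mean_rh98`, `mean_cover`, `mean_pai`, `mean_agbd`,
#'   `mean_agcd`, `qualified`.
#' @export
aggregate_to_cells <- function(shots, cells, min_shots = 5,
                               shots_unfiltered = NULL,
                               carbon_factor = 0.49) {
  stopifnot_cols(shots, c("cell_id", "rh98", "canopy_cover", "pai", "agbd"),
                 "footprint table")
  stopifnot_cols(cells, "cell_id", "cell table")
  unknown <- setdiff(unique(shots$cell_id), cells$cell_id)
  if (length(unknown) > 0) {
    stop("shots reference unknown cell_id(s): ",
         paste(utils::head(sort(unknown), 10), collapse = ", "),
         if (length(unknown) > 10) " ..." else "", call. = FALSE)
  }

  ids <- cells$cell_id
  idx <- match(shots$cell_id, ids)
  n_pass <- tabulate(idx, nbins = length(ids))
  cell_mean <- function(v) {
    s <- rowsum(v, group = idx, reorder = TRUE)
    out <- rep(NA_real_, length(ids))
    out[as.integer(rownames(s))] <- s[, 1]
    out / ifelse(n_pass > 0, n_pass, NA_real_)
  }
  n_total <- n_pass
  if (!is.null(shots_unfiltered)) {
    n_total <- tabulate(match(shots_unfiltered$cell_id, ids),
                        nbins = length(ids))
  }
  out <- data.frame(
    cell_id = ids,
    n_shots_total = n_total,
    n_shots_pass = n_pass,
    mean_rh98 = cell_mean(shots$rh98),
    mean_cover = cell_mean(shots$canopy_cover),
    mean_pai = cell_mean(shots$pai),
    mean_agbd = cell_mean(shots$agbd)
  )
  out$mean_agcd <- ifelse(is.na(out$mean_agbd), NA_real_,
                          agbd_to_agcd(out$mean_agbd, carbon_factor))
  out$qualified <- out$n_shots_pass >= min_shots
  na_cols <- c("mean_rh98", "mean_cover", "mean_pai", "mean_agbd", "mean_agcd")
  out[!out$qualified, na_cols] <- NA_real_
  out
}
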