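# Forest-loss comparison and the five-way effectiveness classification.

effect_class_levels <- function() {
  c("avoided_deforestation", "enhanced_stocks", "no_additionality",
    "encroachment", "degradation")
}

#' Forest-cover-loss fractions inside PAs and their counterfactuals
#'
#' Mean 2000-2019 loss fraction over a group's matched PA cells and over
#' the corresponding matched control cells (cells are equal-area, so the
#' unweighted mean is the area-weighted mean).
#'
#' @param pairs Pair table from [match_cells()] (`$pairs`).
#' @param cells Cell table with `loss_fraction`.
#' @param by Grouping columns on the pair table (default `"pa_id"`), or
#'   `"globe"`.
#' @return Data frame: key columns, `n_pairs`, `loss_pa`, `loss_control`.
#' @export
loss_fractions <- function(pairs, cells, by = "pa_id") {
  if (nrow(pairs) == 0) return(data.frame())
  stopifnot_cols(cells, "loss_fraction", "cell table")
  lp <- cells$loss_fraction[match(pairs$pa_cell_id, cells$cell_id)]
  lc <- cells$loss_fraction[match(pairs$control_cell_id, cells$cell_id)]
  if (identical(by, "globe")) {
    key <- data.frame(stratum = rep("globe", nrow(pairs)))
  } else {
    stopifnot_cols(pairs, by, "pair table")
    key <- pairs[, by, drop = FALSE]
  }
  groups <- split(seq_len(nrow(pairs)), key, drop = TRUE)
  rows <- lapply(groups, function(ix) {
    cbind(key[ix[1], , drop = FALSE],
          data.frame(n_pairs = length(ix),
                     loss_pa = mean(lp[ix]),
                     loss_control = mean(lc[ix])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify protected areas into the five effectiveness classes
#'
#' Each PA's AGBD difference (PA minus counterfactual, Mg/ha) and the loss
#' fractions inside and outside determine its class:
#' * `diff > zero_halfwidth` with more loss outside than inside:
#'   `avoided_deforestation`; otherwise `enhanced_stocks` (avoided
#'   degradation and/or enhanced growth). Differences in the band
#'   `(zero_halfwidth, pos_threshold]` are assigned to the positive branch
#'   with `gap_band_flag = TRUE`.
#' * `|diff| <= zero_halfwidth`: `no_additionality`, regardless of loss.
#' * `diff < -zero_halfwidth` with more loss inside: `encroachment`
#'   (loss visible within the PA); otherwise `degradation`.
#'
#' Ties in loss (`loss_control == loss_pa`) go to `enhanced_stocks` on the
#' positive side and `degradation` on the negative side.
#'
#' @param diff_agbd PA-minus-counterfactual mean AGBD difference, Mg/ha.
#' @param loss_pa,loss_control Loss fractions in `[0, 1]`.
#' @param pos_threshold Threshold for an unflagged positive difference
#'   (default 5 Mg/ha).
#' @param zero_halfwidth Half-width of the no-additionality band
#'   (default 2.5 Mg/ha).
#' @return Data frame with the inputs, `effect_class` (factor over the
#'   five classes) and `gap_band_flag`.
#' @export
classify_pa <- function(diff_agbd, loss_pa, loss_control,
                        pos_threshold = 5, zero_halfwidth = 2.5) {
  if (any(!is.finite(diff_agbd)) || any(!is.finite(loss_pa)) ||
      any(!is.finite(loss_control))) {
    stop("diff_agbd, loss_pa and loss_control must all be finite",
         call. = FALSE)
  }
  if (zero_halfwidth < 0 || pos_threshold < zero_halfwidth) {
    stop("need 0 <= zero_halfwidth <= pos_threshold", call. = FALSE)
  }
  cls <- ifelse(
    abs(diff_agbd) <= zero_halfwidth, "no_additionality",
    ifelse(diff_agbd > zero_halfwidth,
           ifelse(loss_control > loss_pa, "avoided_deforestation",
                  "enhanced_stocks"),
           ifelse(loss_pa > loss_control, "encroachment", "degradation"))
  )
  data.frame(
    diff_agbd = diff_agbd, loss_pa = loss_pa, loss_control = loss_control,
    effect_class = factor(cls, levels = effect_class_levels()),
    gap_band_flag = diff_agbd > zero_halfwidth & diff_agbd <= pos_threshold
  )
}

#' Per-PA effectiveness records
#'
#' Joins per-PA matched AGBD differences and loss fractions and applies
#' [classify_pa()]. Only matched PAs with loss data are classified.
#'
#' @param pa_diff Per-PA table from [stratum_difference()] (`by = "pa_id"`).
#' @param lf Per-PA table from [loss_fractions()].
#' @param pas PA table (for country/continent/biome labels).
#' @inheritParams classify_pa
#' @return Data frame of effectiveness records, one row per classified PA.
#' @export
attribute_effectiveness <- function(pa_diff, lf, pas,
                                    pos_threshold = 5, zero_halfwidth = 2.5) {
  ids <- intersect(pa_diff$pa_id, lf$pa_id)
  di <- pa_diff[match(ids, pa_diff$pa_id), ]
  li <- lf[match(ids, lf$pa_id), ]
  cl <- classify_pa(di$mean_diff_agbd, li$loss_pa, li$loss_control,
                    pos_threshold, zero_halfwidth)
  pi <- match(ids, pas$pa_id)
  data.frame(
    pa_id = ids,
    country = pas$country[pi], continent = pas$continent[pi],
    biome = pas$biome[pi],
    n_pairs = di$n_pairs,
    cl
  )
}

#' Class shares of the effectiveness partition
#'
#' Fraction of classified PAs in each of the five classes, overall or per
#' group; shares over each group sum to 1.
#'
#' @param records Output of [attribute_effectiveness()] (or any table with
#'   an `effect_class` factor).
#' @param by Optional grouping column (e.g. `"continent"`).
#' @return Data frame with `effect_class`, `n`, `share` (plus the grouping
#'   column when `by` is given). Empty input gives an empty table.
#' @export
class_shares <- function(records, by = NULL) {
  if (is.null(records) || nrow(records) == 0) return(data.frame())
  f <- factor(records$effect_class, levels = effect_class_levels())
  one <- function(fx, extra = NULL) {
    tab <- table(fx)
    out <- data.frame(effect_class = names(tab), n = as.integer(tab),
                      share = as.numeric(tab) / sum(tab))
    if (!is.null(extra)) out <- cbind(extra, out, row.names = NULL)
    out
  }
  if (is.null(by)) return(one(f))
  groups <- split(seq_along(f), records[[by]], drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    one(f[groups[[nm]]], stats::setNames(data.frame(nm), by))
  }))
  rownames(out) <- NULL
  out
}
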