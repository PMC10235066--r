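# End-to-end pipeline over a synthetic landscape, run manifest, and the
# derived-share arithmetic applied to printed totals.

#' Pipeline configuration
#'
#' Bundles the landscape configuration with every stage parameter; all
#' values are echoed into the run manifest so a run can be reproduced from
#' its manifest alone.
#'
#' @param landscape A [landscape_config()].
#' @param buffer_km PA buffer for control eligibility, km.
#' @param caliper_width_sd Caliper width as a multiple of SD(logit scores).
#' @param caliper Optional fixed score-gap caliper overriding the rule.
#' @param min_shots Minimum passing shots per qualified cell.
#' @param sensitivity_threshold Minimum per-shot sensitivity.
#' @param carbon_factor AGBD-to-AGCD conversion factor.
#' @param pos_threshold,zero_halfwidth Classification thresholds, Mg/ha.
#' @param model_rel_se Relative model-error term of the hybrid variance.
#' @param match_rule `"nearest"` or `"max_score"`.
#' @param seed Overrides the landscape seed, so one integer controls the
#'   whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       buffer_km = 10,
                       caliper_width_sd = 0.2,
                       caliper = NULL,
                       min_shots = 5,
                       sensitivity_threshold = 0.95,
                       carbon_factor = 0.49,
                       pos_threshold = 5,
                       zero_halfwidth = 2.5,
                       model_rel_se = 0.02,
                       match_rule = "nearest",
                       seed = NULL) {
  if (!is.null(seed)) landscape$seed <- as.integer(seed)
  structure(list(
    landscape = landscape, buffer_km = buffer_km,
    caliper_width_sd = caliper_width_sd, caliper = caliper,
    min_shots = min_shots, sensitivity_threshold = sensitivity_threshold,
    carbon_factor = carbon_factor, pos_threshold = pos_threshold,
    zero_halfwidth = zero_halfwidth, model_rel_se = model_rel_se,
    match_rule = match_rule, seed = landscape$seed
  ), class = "run_config")
}

#' Run the full pipeline on a synthetic landscape
#'
#' Generates the landscape and footprints, quality-filters and aggregates
#' shots to cells, builds the matching pools, fits the propensity model,
#' matches, estimates per-PA and aggregated additionally preserved carbon,
#' classifies PAs into the five effectiveness classes, and runs the
#' baseline placement check. Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as CSV plus a JSON `manifest.json` (configuration, seed and
#'   stage counts).
#' @return A list (class `pacarbon_run`) with elements `landscape`,
#'   `cell_metrics`, `pools`, `model`, `caliper`, `match`, `balance`,
#'   `estimates`, `loss`, `records`, `shares`, `baseline`, `counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ls <- generate_landscape(config$landscape)
  fp <- sample_footprints(ls)
  fpf <- filter_footprints(fp, config$sensitivity_threshold)
  cm <- aggregate_to_cells(fpf, ls$cells, min_shots = config$min_shots,
                           shots_unfiltered = fp,
                           carbon_factor = config$carbon_factor)
  pools <- build_control_pool(ls$cells, ls$pas, config$buffer_km, cm)
  model <- fit_propensity(pools$treated, pools$controls)
  cal <- if (!is.null(config$caliper)) {
    list(support = c(max(model$range_treated[1], model$range_control[1]),
                     min(model$range_treated[2], model$range_control[2])),
         caliper = config$caliper)
  } else {
    set_caliper(model, config$caliper_width_sd)
  }
  mt <- match_cells(pools$treated, pools$controls, model, cal,
                    match_rule = config$match_rule)
  bal <- balance_report(pools, mt, model)
  est <- estimate_effects(mt, cm, ls$cells, ls$pas,
                          model_rel_se = config$model_rel_se)
  pa_diff <- stratum_difference(mt$pairs, cm, by = "pa_id")
  lf <- loss_fractions(mt$pairs, ls$cells, by = "pa_id")
  rec <- attribute_effectiveness(pa_diff, lf, ls$pas,
                                 config$pos_threshold,
                                 config$zero_halfwidth)
  shares <- class_shares(rec)
  bl <- baseline_differences(mt$pairs, ls$cells, ls$pas)
  reg <- tryCatch(age_regression(bl, by_forest = TRUE),
                  error = function(e) NULL)

  counts <- list(
    n_shots = nrow(fp), n_shots_pass = nrow(fpf),
    n_cells = nrow(ls$cells), n_cells_qualified = sum(cm$qualified),
    n_treated = nrow(pools$treated), n_controls = nrow(pools$controls),
    n_pairs = nrow(mt$pairs), n_unmatched = nrow(mt$unmatched)
  )
  manifest <- list(config = manifest_config(config), counts = counts)
  out <- structure(list(
    landscape = ls, cell_metrics = cm, pools = pools, model = model,
    caliper = cal, match = mt, balance = bal, estimates = est,
    loss = lf, records = rec, shares = shares,
    baseline = list(records = bl,
                    summary = if (nrow(bl)) baseline_group_summary(bl) else NULL,
                    regression = reg),
    counts = counts, manifest = manifest
  ), class = "pacarbon_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$landscape <- unclass(cfg$landscape)
  cfg
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(run$match$pairs, "pairs.csv")
  w(run$balance, "balance.csv")
  w(run$estimates$pa_table, "pa_estimates.csv")
  w(run$estimates$stratum_table, "stratum_estimates.csv")
  w(run$estimates$by_country, "by_country.csv")
  w(run$estimates$by_continent, "by_continent.csv")
  w(run$estimates$by_biome, "by_biome.csv")
  w(run$estimates$globe, "globe.csv")
  w(run$records, "effectiveness_records.csv")
  w(run$shares, "class_shares.csv")
  if (nrow(run$baseline$records)) w(run$baseline$records, "baseline_records.csv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pacarbon_run <- function(x, ...) {
  g <- x$estimates$globe
  cat(sprintf("pacarbon_run: %d pairs from %d treated cells; global additional C = %.4g Gt (SE %.3g)\n",
              x$counts$n_pairs, x$counts$n_treated,
              g$additional_gt, g$se_additional_gt))
  invisible(x)
}

#' Integer-percent share
#'
#' `round(100 * numerator / denominator)` - the rounding used for shares
#' printed to whole percent.
#'
#' @param numerator,denominator Totals in the same unit.
#' @return Integer percentage (`NA` with a warning for zero denominators).
#' @export
share_integer_pct <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    warning("zero denominator in share computation", call. = FALSE)
    return(ifelse(denominator == 0, NA_real_,
                  round(100 * numerator / denominator)))
  }
  round(100 * numerator / denominator)
}

#' One-decimal truncated-percent share
#'
#' `floor(1000 * numerator / denominator) / 10` - percentages printed to
#' one decimal are truncated, not rounded.
#'
#' @inheritParams share_integer_pct
#' @return Percentage truncated to one decimal.
#' @export
share_truncate1_pct <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    warning("zero denominator in share computation", call. = FALSE)
    return(ifelse(denominator == 0, NA_real_,
                  floor(1000 * numerator / denominator) / 10))
  }
  floor(1000 * numerator / denominator) / 10
}

#' Derived shares from carbon totals
#'
#' Computes the share of total aboveground carbon stored in PAs (whole
#' percent), each country's share of the global additionally preserved
#' carbon (one-decimal truncated percent) with a top-ranked subset, and
#' optionally each country's protected share of its national carbon. The
#' totals may come from a pipeline run or be hand-entered printed values,
#' so published numbers can be pushed through the same arithmetic.
#'
#' @param pa_agc_gt Total PA carbon, Gt.
#' @param domain_agc_gt Total (domain-wide) carbon, Gt.
#' @param additional_by_country Optional data frame with `country` and
#'   `additional_gt`.
#' @param global_additional_gt Global additionally preserved carbon, Gt
#'   (denominator of the country shares).
#' @param national_agc Optional data frame with `country`, `pa_agc_gt`,
#'   `national_agc_gt` for protected-share percentages.
#' @param top_n Size of the country ranking (default 20).
#' @return List with `pa_share_pct`, `country_shares` (ranked, with
#'   `share_pct`), `top`, and `protected_share` when `national_agc` is
#'   given.
#' @export
derived_shares <- function(pa_agc_gt = NULL, domain_agc_gt = NULL,
                           additional_by_country = NULL,
                           global_additional_gt = NULL,
                           national_agc = NULL, top_n = 20) {
  out <- list()
  if (!is.null(pa_agc_gt) && !is.null(domain_agc_gt)) {
    out$pa_share_pct <- share_integer_pct(pa_agc_gt, domain_agc_gt)
  }
  if (!is.null(additional_by_country) && !is.null(global_additional_gt)) {
    stopifnot_cols(additional_by_country, c("country", "additional_gt"),
                   "country table")
    tb <- additional_by_country
    tb$share_pct <- share_truncate1_pct(tb$additional_gt,
                                        global_additional_gt)
    tb <- tb[order(-tb$additional_gt, tb$country), , drop = FALSE]
    tb$rank <- seq_len(nrow(tb))
    rownames(tb) <- NULL
    out$country_shares <- tb
    out$top <- utils::head(tb, top_n)
  }
  if (!is.null(national_agc)) {
    stopifnot_cols(national_agc, c("country", "pa_agc_gt", "national_agc_gt"),
                   "national totals table")
    ps <- national_agc
    ps$protected_share_pct <- share_integer_pct(ps$pa_agc_gt,
                                                ps$national_agc_gt)
    out$protected_share <- ps
  }
  out
}
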