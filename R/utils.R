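# internal helpers shared across stages

# standardize a numeric vector; constant vectors map to all-zero rather than NaN
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# standardized mean difference with pooled (average-of-variances) denominator
smd <- function(x_treated, x_control) {
  denom <- sqrt((stats::var(x_treated) + stats::var(x_control)) / 2)
  if (!is.finite(denom) || denom == 0) return(0)
  (mean(x_treated) - mean(x_control)) / denom
}

#' Quantitative covariates used for propensity-score matching
#'
#' The geophysical, climatic and socioeconomic covariates entering the
#' logistic propensity model. Categorical covariates (land cover, country,
#' ecoregion, biome) are matched exactly instead and are not listed here.
#'
#' @return Character vector of column names on the cell table.
#' @export
pa_covariates <- function() {
  c("elevation", "slope", "precip", "tmin", "tmax",
    "dist_city", "dist_road", "travel_time", "pop_count", "pop_density")
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
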